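# shared fixtures for the suite; everything is generated in code

# a bare single-atom "ion" with configurable charge: spherical test system
single_atom <- function(element = "C", charge = 0) {
  molecular_ion(
    data.frame(element = element, x = 0, y = 0, z = 0,
               partial_charge = charge),
    total_charge = charge, name = paste0(element, "-atom")
  )
}

# the radial LJ potential a single-atom ion presents to the N2-iso gas site
lj_radial <- function(element = "C", gas = drift_gas("N2-iso")) {
  row <- gas$lj[gas$lj$element == element, ]
  function(r) 4 * row$epsilon * ((row$sigma / r)^12 - (row$sigma / r)^6)
}

# central finite-difference gradient of the potential at a point
fd_force <- function(ion, gas, center, axis = c(0, 0, 1), h = 1e-5) {
  vapply(1:3, function(k) {
    e <- rep(0, 3); e[k] <- h
    -(potential_energy(ion, gas, center + e, axis) -
        potential_energy(ion, gas, center - e, axis)) / (2 * h)
  }, 0)
}

# hard-sphere deflection function of diameter d (angle in rad)
hard_sphere_chi <- function(d) {
  function(b, g) ifelse(b < d, 2 * acos(pmin(b / d, 1)), 0)
}

# all pairwise interatomic distances of an ion
pair_distances <- function(ion) {
  as.vector(stats::dist(ion_coords(ion)))
}
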
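#' Ion-gas interaction energy
#'
#' Evaluates the rigid-ion interaction potential seen by a drift-gas probe:
#' pairwise 12-6 Lennard-Jones terms between the ion's atoms and the gas LJ
#' sites, the charge-induced-dipole term `-(alpha/2) |E|^2` built from the
#' ion's partial charges at the gas center, and (for multi-site gases)
#' Coulomb terms between the partial charges and the gas point charges that
#' represent its quadrupole moment. Collisions governed by this potential
#' are elastic: it depends only on the relative geometry.
#'
#' @param ion A [molecular_ion()].
#' @param gas A [drift_gas()].
#' @param gas_center Length-3 position of the gas center, Angstrom.
#' @param gas_axis Length-3 orientation axis of the gas (normalized
#'   internally; only meaningful for multi-site gases).
#' @return Energy in meV.
#' @examples
#' v <- potential_energy(build_water_cluster(0), drift_gas("N2-iso"), c(8, 0, 0))
#' @export
potential_energy <- function(ion, gas, gas_center, gas_axis = c(0, 0, 1)) {
  .potential_raw(ion, gas, gas_center, gas_axis)$energy
}

#' Force on the drift-gas probe
#'
#' Analytic negative gradient of [potential_energy()] with respect to the gas
#' center position (the whole rigid gas translated). For multi-site gases the
#' torque about the gas center is attached as attribute `"torque"`
#' (meV, i.e. meV*A/rad); the trajectory engine freezes the gas orientation,
#' so torque is diagnostic only.
#'
#' @inheritParams potential_energy
#' @return Length-3 force vector, meV/Angstrom.
#' @export
force <- function(ion, gas, gas_center, gas_axis = c(0, 0, 1)) {
  out <- .potential_raw(ion, gas, gas_center, gas_axis)
  structure(out$force, torque = out$torque)
}

.gas_cpp <- function(gas) {
  list(offset = gas$sites$offset, lj = as.integer(gas$sites$lj),
       charge = gas$sites$charge, alpha = gas$alpha)
}

.potential_raw <- function(ion, gas, gas_center, gas_axis) {
  stopifnot(inherits(ion, "molecular_ion"), inherits(gas, "drift_gas"))
  if (length(gas_center) != 3 || !all(is.finite(gas_center))) {
    stop("gas_center must be a finite length-3 vector", call. = FALSE)
  }
  nrm <- sqrt(sum(gas_axis^2))
  if (!is.finite(nrm) || nrm == 0) stop("gas_axis must be nonzero", call. = FALSE)
  lj <- .lj_for_ion(ion, gas)
  cpp_potential(ion_coords(ion), ion$atoms$partial_charge, lj$epsilon,
                lj$sigma, .gas_cpp(gas), as.numeric(gas_center),
                as.numeric(gas_axis / nrm))
}
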
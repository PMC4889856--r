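test_that("potential has the right limits and superposition structure", {
  gas <- drift_gas("N2-iso")
  ion <- build_water_cluster(1)
  # vanishes at infinity (r^-4 tail: ~2e-7 meV at 500 A)
  expect_lt(abs(potential_energy(ion, gas, c(500, 0, 0))), 1e-6)
  expect_lt(abs(potential_energy(ion, gas, c(0, 0, 5000))), 1e-10)

  # zero partial charges: potential is the bare LJ sum
  neutral <- single_atom("C", 0)
  row <- gas$lj[gas$lj$element == "C", ]
  r <- 4.1
  v <- potential_energy(neutral, gas, c(r, 0, 0))
  expect_equal(v, 4 * row$epsilon * ((row$sigma / r)^12 - (row$sigma / r)^6),
               tolerance = 1e-12)
  # ... and exactly zero at r = sigma
  expect_equal(potential_energy(neutral, gas, c(row$sigma, 0, 0)), 0,
               tolerance = 1e-12)

  # guard radius trips a clear error
  expect_error(potential_energy(ion, gas, c(0.05, 0, 0)), "near-singularity")
  expect_error(.lj_check <- potential_energy(single_atom("Cl", 0), gas,
                                             c(5, 0, 0)), "no LJ parameters")
})

test_that("analytic forces match central finite differences to 1e-5", {
  set.seed(7)
  cases <- list(
    list(ion = build_water_cluster(1), gas = drift_gas("N2-iso")),
    list(ion = build_benzene(TRUE), gas = drift_gas("N2")),
    list(ion = single_atom("C", 1), gas = drift_gas("N2"))
  )
  for (cs in cases) {
    for (i in 1:4) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      p <- dir * runif(1, 4.5, 9)
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      f <- force(cs$ion, cs$gas, p, ax)
      fd <- fd_force(cs$ion, cs$gas, p, ax)
      expect_equal(as.numeric(f), fd, tolerance = 1e-5)
    }
  }
})

test_that("energy is invariant under joint rigid transforms", {
  ion <- build_toluene(TRUE)
  gas <- drift_gas("N2")
  center <- c(5.5, 1, -2); axis <- c(0, 0, 1)
  v0 <- potential_energy(ion, gas, center, axis)
  set.seed(11)
  for (rr in random_rotation(4)) {
    tr <- c(2, -5, 1)
    v1 <- potential_energy(rigid_transform(ion, rr, tr), gas,
                           as.numeric(rr %*% center) + tr,
                           as.numeric(rr %*% axis))
    expect_equal(v1, v0, tolerance = 1e-9)
  }
})

test_that("charged ions have an attractive r^-4 long-range tail", {
  gas <- drift_gas("N2-iso")
  for (ion in list(build_water_cluster(0), build_alkane(8, TRUE))) {
    rs <- seq(15, 40, length.out = 12)
    vs <- vapply(rs, function(r) potential_energy(ion, gas, c(0, r, 0)), 0)
    expect_true(all(vs < 0))
    slope <- coef(lm(log(-vs) ~ log(rs)))[[2]]
    expect_equal(slope, -4, tolerance = 0.05 / 4)  # -4 +/- 0.05
  }
})

test_that("multi-site N2 has zero net charge and reports torque", {
  gas <- drift_gas("N2")
  expect_equal(sum(gas$sites$charge), 0)
  f <- force(build_water_cluster(0), gas, c(4.5, 1, 0), c(1, 1, 0) / sqrt(2))
  expect_length(attr(f, "torque"), 3)
  expect_gt(max(abs(attr(f, "torque"))), 0)
})

test_that("gas models load from YAML and JSON configs", {
  gas <- drift_gas("N2")
  cfg <- list(name = "N2-custom", mass = gas$mass, alpha = gas$alpha,
              sites = lapply(seq_len(nrow(gas$sites)), function(i) {
                list(offset = gas$sites$offset[i], lj = gas$sites$lj[i],
                     charge = gas$sites$charge[i])
              }),
              lj = setNames(lapply(seq_len(nrow(gas$lj)), function(i) {
                list(epsilon = gas$lj$epsilon[i], sigma = gas$lj$sigma[i])
              }), gas$lj$element))
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  gy <- read_gas_config(fy)
  expect_equal(gy$mass, gas$mass)
  expect_equal(gy$lj$epsilon[gy$lj$element == "C"],
               gas$lj$epsilon[gas$lj$element == "C"])
  # identical physics through either description
  ion <- build_water_cluster(0)
  expect_equal(potential_energy(ion, gy, c(4, 0, 1)),
               potential_energy(ion, gas, c(4, 0, 1)), tolerance = 1e-12)

  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE, digits = NA)
  gj <- read_gas_config(fj)
  expect_equal(potential_energy(ion, gj, c(4, 0, 1)),
               potential_energy(ion, gas, c(4, 0, 1)), tolerance = 1e-12)

  bad <- cfg; bad$sites[[1]]$charge <- 0.2
  fb <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, fb)
  expect_error(read_gas_config(fb), "sum to zero")
})
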
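test_that("Mason-Schamp matches an independently derived reference value", {
  # frozen from a constant-by-constant SI dimensional-analysis evaluation
  # (CODATA constants, omega 100 A^2, m 91 Da, M 28 Da, T 298 K, q 1 e,
  # N the standard 273.15 K / 101325 Pa number density)
  K <- mason_schamp(100, m = 91, M = 28, q = 1, temperature = 298,
                    number_density = physical_constants()$loschmidt)
  expect_equal(K$K, 2.317228821313709, tolerance = 1e-6)
})

test_that("Mason-Schamp scalings: inverse in omega, linear in charge", {
  base <- mason_schamp(100, 91, 28.014, 1, 298)
  expect_equal(mason_schamp(200, 91, 28.014, 1, 298)$K, base$K / 2,
               tolerance = 1e-12)
  expect_equal(mason_schamp(100, 91, 28.014, 2, 298)$K, base$K * 2,
               tolerance = 1e-12)
  # property over random valid inputs
  set.seed(8)
  for (i in 1:10) {
    om <- runif(1, 30, 400); m <- runif(1, 15, 600); temp <- runif(1, 200, 500)
    s <- runif(1, 0.5, 3)
    expect_equal(mason_schamp(s * om, m, 28.014, 1, temp)$K,
                 mason_schamp(om, m, 28.014, 1, temp)$K / s,
                 tolerance = 1e-12)
  }
  expect_error(mason_schamp(-5, 91, 28, 1, 298), "positive")
})

test_that("reduced mobility K0 is invariant across operating conditions", {
  pc <- physical_constants()
  # same T: K0 is independent of the operating pressure / number density
  ks <- lapply(c(0.5, 1, 2), function(patm) {
    N <- patm * 101325 / (pc$k_B * 298) * 1e-6
    mason_schamp(120, 91, 28.014, 1, 298, number_density = N)
  })
  expect_equal(ks[[1]]$K0, ks[[2]]$K0, tolerance = 1e-9)
  expect_equal(ks[[3]]$K0, ks[[2]]$K0, tolerance = 1e-9)
  # across T (fixed omega), K0 carries only the explicit 1/sqrt(T) factor
  k223 <- mason_schamp(120, 91, 28.014, 1, 223)
  expect_equal(k223$K0, ks[[2]]$K0 * sqrt(298 / 223), tolerance = 1e-9)
})

test_that("drift-time conversion is exact and self-inverse", {
  geom <- instrument_geometry(L = 5.5, U = 1925)
  # direct arithmetic: K = L^2 / (t_D U) = 30.25 / 11.55
  K <- mobility_from_drift(geom, measured_peak(6.0))
  expect_equal(K$K, 30.25 / 11.55, tolerance = 1e-12)
  expect_equal(K$K, 2.619, tolerance = 1e-3)
  # round-trip identity
  t_back <- drift_from_mobility(geom, K)
  expect_equal(t_back, 6.0, tolerance = 1e-12)
  K2 <- mobility_from_drift(instrument_geometry(5.5, 2 * 1925), 6.0)
  expect_equal(K2$K, K$K / 2, tolerance = 1e-12)
  expect_error(mobility_from_drift(geom, -1), "positive")
})

test_that("the Langevin-limit O2 correction has the right structure", {
  # degenerate gases: identical properties leave K unchanged
  same <- list(n2 = gas_properties("N2"),
               o2 = gas_properties("O2", mass = 28.014,
                                   dielectric = 1.000548))
  expect_equal(o2_from_n2(2.0, 91, same), 2.0, tolerance = 1e-12)

  # heavy-analyte limit: ratio -> sqrt((D_N2-1) M_N2 / ((D_O2-1) M_O2))
  props <- list(n2 = gas_properties("N2"), o2 = gas_properties("O2"))
  lim <- sqrt((1.000548 - 1) * 28.014 / ((1.000495 - 1) * 31.998))
  expect_equal(o2_from_n2(1.0, 1e6, props), lim, tolerance = 1e-5)
  expect_equal(o2_from_n2(1.0, 1e9, props), lim, tolerance = 1e-8)

  # m = 91 against an independently hand-evaluated ratio
  expect_equal(o2_from_n2(1.0, 91, props), 1.0008380862866955,
               tolerance = 1e-9)
  bad <- list(n2 = gas_properties("N2"),
              o2 = list(name = "O2", mass = 31.998, dielectric = 0.9))
  expect_error(o2_from_n2(1.0, 91, bad), "dielectric")
})

test_that("Blanc's law mixes harmonically and stays between components", {
  expect_equal(blanc_mix(2.5, 1), 2.5)
  expect_equal(blanc_mix(c(1.7, 1.7, 1.7), c(0.2, 0.3, 0.5)), 1.7,
               tolerance = 1e-12)
  expect_equal(blanc_mix(c(2.000, 1.900), c(0.79, 0.21)),
               1 / (0.79 / 2.000 + 0.21 / 1.900), tolerance = 1e-12)
  expect_equal(blanc_mix(c(2.000, 1.900), c(0.79, 0.21)), 1.9781,
               tolerance = 1e-4)
  set.seed(12)
  for (i in 1:10) {
    K <- runif(3, 0.5, 4)
    x <- runif(3); x <- x / sum(x)
    mix <- blanc_mix(K, x)
    expect_gte(mix, min(K)); expect_lte(mix, max(K))
  }
  expect_error(blanc_mix(numeric(0), numeric(0)), "no components")
  expect_error(blanc_mix(c(2, 1.9), c(0.8, 0.1)), "sum to 1")
})

test_that("air and nitrogen mobilities differ by less than 3 percent", {
  for (m in c(19, 37, 78, 91, 92, 142)) {
    K_air <- air_from_n2(2.0, m)
    expect_lt(abs(K_air - 2.0) / 2.0, 0.03)
    # mixture betweenness
    K_o2 <- o2_from_n2(2.0, m)
    expect_gte(K_air, min(2.0, K_o2) - 1e-12)
    expect_lte(K_air, max(2.0, K_o2) + 1e-12)
  }
  expect_equal(air_from_n2(2.0, 91, c(N2 = 1, O2 = 0)), 2.0,
               tolerance = 1e-12)
  # mobility_value inputs keep their conditions metadata
  mv <- mason_schamp(110, 91, 28.014, 1, 298)
  out <- air_from_n2(mv, 91)
  expect_s3_class(out, "mobility_value")
  expect_equal(unname(out$conditions$composition["O2"]), 0.21)
})
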
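test_that("velocity quadrature is normalized, convergent and T-scaling", {
  vq <- velocity_quadrature(298, 11.3, 16)
  expect_equal(sum(vq$weight), 1, tolerance = 1e-12)
  # constant integrand reproduced exactly
  expect_equal(sum(vq$weight * 42), 42, tolerance = 1e-12)
  # refinement: a smooth function's weighted mean is stable at n >= 32
  smooth_fn <- function(g) 1 / (1 + (g / 8)^2)
  m32 <- with(velocity_quadrature(298, 11.3, 32), sum(weight * smooth_fn(g)))
  m64 <- with(velocity_quadrature(298, 11.3, 64), sum(weight * smooth_fn(g)))
  expect_equal(m32, m64, tolerance = 1e-6)
  # nodes scale as sqrt(T)
  vq4 <- velocity_quadrature(4 * 298, 11.3, 16)
  expect_equal(vq4$g, 2 * vq$g, tolerance = 1e-12)
  expect_equal(vq4$weight, vq$weight)
})

test_that("hard-sphere deflection plug-in returns pi d^2 exactly", {
  ion <- build_water_cluster(0)
  gas <- drift_gas("N2-iso")
  for (d in c(2, 3, 4.5)) {
    # independent of temperature and of the molecule carrying the plug-in
    for (temp in c(150, 298)) {
      res <- compute_ccs(ion, gas, temp,
                         sampling_plan(20, 6, 12, seed = 3, b_max = d),
                         chi_fun = hard_sphere_chi(d))
      expect_equal(res$omega, pi * d^2, tolerance = 1e-12)
      expect_equal(res$stderr, 0, tolerance = 1e-12)
    }
  }
})

test_that("identical plans (seed included) give bit-identical results", {
  ion <- build_water_cluster(0)
  gas <- drift_gas("N2-iso")
  plan <- sampling_plan(16, 4, 8, seed = 99, b_max = 20)
  r1 <- compute_ccs(ion, gas, 298, plan)
  r2 <- compute_ccs(ion, gas, 298, plan)
  expect_identical(r1$omega, r2$omega)
  expect_identical(r1$stderr, r2$stderr)
  # and the R session RNG stream is left untouched
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(compute_ccs(ion, gas, 298, plan)); after <- runif(3)
  expect_identical(before, after)
})

test_that("cross sections are invariant under rigid rotation of the ion", {
  ion <- build_benzene(TRUE)
  gas <- drift_gas("N2-iso")
  plan <- sampling_plan(64, 8, 24, seed = 21, b_max = 28)
  r0 <- compute_ccs(ion, gas, 298, plan)
  set.seed(1234)
  rot <- random_rotation(1)[[1]]
  r1 <- compute_ccs(rigid_transform(ion, rot), gas, 298, plan)
  se <- sqrt(r0$stderr^2 + r1$stderr^2)
  expect_lt(abs(r1$omega - r0$omega), 3 * se)
})

test_that("b_max search tracks molecular size and stays finite", {
  gas <- drift_gas("N2-iso")
  b_small <- choose_bmax(build_water_cluster(0), gas, 298)
  b_large <- choose_bmax(build_alkane(10, TRUE), gas, 298)
  expect_gt(b_large, b_small)
  expect_lt(b_large, 100)
  # zero-charge LJ-only small ion: short-ranged potential, tight cutoff
  b_neutral <- choose_bmax(single_atom("C", 0), gas, 298)
  expect_lt(b_neutral, 25)
  expect_gt(b_neutral, 2)
})

test_that("omega is insensitive to the b_max safety margin", {
  ion <- build_water_cluster(0)
  gas <- drift_gas("N2-iso")
  b0 <- choose_bmax(ion, gas, 298) / 1.2  # converged cutoff before margin
  r1 <- compute_ccs(ion, gas, 298, sampling_plan(48, 8, 24, seed = 5,
                                                 b_max = b0))
  r2 <- compute_ccs(ion, gas, 298, sampling_plan(48, 8, 24, seed = 5,
                                                 b_max = 1.2 * b0))
  se <- sqrt(r1$stderr^2 + r2$stderr^2)
  expect_lt(abs(r1$omega - r2$omega), max(se, 0.01 * r1$omega))
})

test_that("spherical-system omega matches the product-quadrature oracle", {
  atom <- single_atom("C", 0)
  gas <- drift_gas("N2-iso")
  Vfun <- lj_radial("C", gas)
  mu <- atom$mass * gas$mass / (atom$mass + gas$mass)
  b_max <- 9
  vq <- velocity_quadrature(298, mu, 16)
  bs <- seq(1e-3, b_max, length.out = 180)
  db <- bs[2] - bs[1]
  omega_oracle <- sum(vq$weight * vapply(vq$g, function(g) {
    chis <- vapply(bs, function(b) deflection_integral_oracle(Vfun, b, g, mu),
                   0)
    sum(2 * pi * bs * (1 - cos(chis))) * db
  }, 0))
  res <- compute_ccs(atom, gas, 298,
                     sampling_plan(24, 16, 12, seed = 17, b_max = b_max))
  expect_lt(abs(res$omega - omega_oracle), 2 * res$stderr)
})

test_that("omega grows from hexane to decane at matched plans", {
  gas <- drift_gas("N2-iso")
  plan <- sampling_plan(64, 6, 16, seed = 31, n_batches = 8)
  r6 <- compute_ccs(build_alkane(6, TRUE), gas, 298, plan)
  r10 <- compute_ccs(build_alkane(10, TRUE), gas, 298, plan)
  expect_gt(r10$omega, r6$omega)
  # the fast projection estimate agrees on the ordering
  expect_gt(ccs_projection(build_alkane(10, TRUE), gas),
            ccs_projection(build_alkane(6, TRUE), gas))
})

test_that("results tidy, serialize and batch over a manifest", {
  ion <- build_water_cluster(0)
  gas <- drift_gas("N2-iso")
  res <- compute_ccs(ion, gas, 298, sampling_plan(10, 4, 8, seed = 2,
                                                  b_max = 25, n_batches = 5))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$omega, res$omega)
  gl <- glance(res)
  expect_equal(gl$seed, 2L)
  f <- withr::local_tempfile(fileext = ".json")
  ccs_to_json(res, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$omega, res$omega)
  expect_equal(back$plan$seed, 2)

  dir <- withr::local_tempdir()
  write_xyzq(build_water_cluster(0), file.path(dir, "h3o.xyzq"))
  write_xyzq(build_water_cluster(1), file.path(dir, "h3o_w1.xyzq"))
  writeLines(c("name,path", "h3o,h3o.xyzq", "h3o_w1,h3o_w1.xyzq"),
             file.path(dir, "manifest.csv"))
  out <- ccs_batch(file.path(dir, "manifest.csv"), gas, 298,
                   sampling_plan(10, 4, 8, seed = 2, b_max = 25,
                                 n_batches = 5))
  expect_equal(nrow(out), 2)
  expect_true(all(out$omega > 0))
  expect_gt(out$omega[2], out$omega[1])  # the hydrate is bigger
})
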
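test_that("xyzq files parse, validate and round-trip losslessly", {
  f <- withr::local_tempfile(fileext = ".xyzq")
  writeLines(c("1", "lone nitrogen charge=+1",
               "N 0.0 0.0 0.0 1.0"), f)
  ion <- read_xyzq(f)
  expect_s3_class(ion, "molecular_ion")
  expect_equal(nrow(ion$atoms), 1)
  expect_equal(ion$mass, 14.007)  # standard atomic weight
  expect_equal(ion$total_charge, 1L)

  # round-trip: numeric content identical to well below 1e-6 A
  for (builder in list(build_water_cluster(2), build_benzene(TRUE),
                       build_alkane(7, TRUE))) {
    g <- withr::local_tempfile(fileext = ".xyzq")
    write_xyzq(builder, g)
    back <- read_xyzq(g)
    expect_equal(ion_coords(back), ion_coords(builder), tolerance = 1e-9)
    expect_lt(max(abs(back$atoms$partial_charge -
                        builder$atoms$partial_charge)), 1e-8)
    expect_identical(back$total_charge, builder$total_charge)
  }

  # charge-sum invariant violation is reported with the discrepancy
  bad <- withr::local_tempfile(fileext = ".xyzq")
  writeLines(c("2", "bad charge=+1",
               "N 0 0 0 0.5", "N 1 0 0 0.45"), bad)
  expect_error(read_xyzq(bad), "0\\.95")

  # malformed atom line names its line number
  mal <- withr::local_tempfile(fileext = ".xyzq")
  writeLines(c("2", "x charge=+1", "N 0 0 0 0.5", "N 1 0 oops"), mal)
  expect_error(read_xyzq(mal), "line 4")
  nocomment <- withr::local_tempfile(fileext = ".xyzq")
  writeLines(c("1", "no total given", "N 0 0 0 1"), nocomment)
  expect_error(read_xyzq(nocomment), "charge=")
})

test_that("molecular_ion enforces its invariants", {
  at <- data.frame(element = "N", x = 0, y = 0, z = 0, partial_charge = 0.95)
  expect_error(molecular_ion(at, total_charge = 1), "tolerance")
  expect_silent(molecular_ion(at, total_charge = 1, charge_tolerance = 0.06))
  expect_error(molecular_ion(at[0, ], total_charge = 0), "at least one atom")
  at$x <- Inf
  expect_error(molecular_ion(at, 1, charge_tolerance = 0.06), "finite")
  expect_error(
    molecular_ion(data.frame(element = "Xx", x = 0, y = 0, z = 0,
                             partial_charge = 1), 1),
    "no tabulated atomic mass")
})

test_that("water-cluster builder produces valid hydronium clusters", {
  for (n in 0:5) {
    ion <- build_water_cluster(n)
    expect_equal(nrow(ion$atoms), 4 + 3 * n)
    expect_identical(ion$total_charge, 1L)
    expect_equal(sum(ion$atoms$partial_charge), 1, tolerance = 1e-12)
    # nominal (integer-rounded) mass follows the 19 + 18 n series
    expect_equal(round(ion$mass), 19 + 18 * n)
    # no atom collisions anywhere in the cluster
    expect_gte(min(pair_distances(ion)), 0.9)
  }
  expect_equal(round(build_water_cluster(4)$mass), 91)
  expect_error(build_water_cluster(-1), "non-negative")
  expect_error(build_water_cluster(6), "at most 5")
})

test_that("aromatic builders give correct formulas and charge sums", {
  benz <- build_benzene()
  expect_equal(nrow(benz$atoms), 12)
  expect_equal(benz$mass, 78.114, tolerance = 1e-6)
  expect_equal(sum(benz$atoms$partial_charge), 1, tolerance = 1e-12)

  bw <- build_benzene(TRUE)
  expect_equal(nrow(bw$atoms), 15)
  expect_equal(sum(bw$atoms$partial_charge), 1, tolerance = 1e-12)
  # water sits on the ring axis ~3 A above the (planar, z = 0) ring
  expect_gte(min(abs(bw$atoms$z[13:15])), 2.4)

  tw <- build_toluene(TRUE)
  expect_equal(nrow(tw$atoms), 18)
  expect_equal(sum(tw$atoms$partial_charge), 1, tolerance = 1e-12)
  expect_equal(build_toluene()$mass, 92.141, tolerance = 1e-6)
})

test_that("alkane builder spans hexane to decane with a clean water adduct", {
  for (n in 6:10) {
    bare <- build_alkane(n)
    expect_equal(nrow(bare$atoms), 3 * n + 2)
    expect_equal(bare$mass, n * 12.011 + (2 * n + 2) * 1.008,
                 tolerance = 1e-6)
    withw <- build_alkane(n, TRUE)
    expect_equal(nrow(withw$atoms), 3 * n + 5)
    expect_equal(sum(withw$atoms$partial_charge), 1, tolerance = 1e-12)
    # water never collides with the chain
    xyz <- ion_coords(withw)
    n_alk <- 3 * n + 2
    d <- as.matrix(stats::dist(xyz))[(n_alk + 1):(n_alk + 3), 1:n_alk]
    expect_gte(min(d), 2.0)
    # realistic bonded geometry: no overlapping atoms
    expect_gte(min(pair_distances(bare)), 1.0)
  }
  expect_error(build_alkane(5), "between 6 and 10")
  expect_error(build_alkane(11), "between 6 and 10")
})

test_that("rigid transforms preserve geometry, charges and masses", {
  ion <- build_toluene(TRUE)
  expect_equal(ion_coords(rigid_transform(ion)), ion_coords(ion))

  # 90 degree rotation about z maps the x-axis onto the y-axis
  two <- molecular_ion(
    data.frame(element = c("N", "N"), x = c(0, 1.1), y = 0, z = 0,
               partial_charge = c(0.5, 0.5)), 1)
  rz <- euler_rotation(pi / 2, 0, 0)
  rot <- rigid_transform(two, rz)
  expect_equal(unname(ion_coords(rot)[2, ]), c(0, 1.1, 0), tolerance = 1e-12)

  # arbitrary rotations leave the full distance matrix unchanged
  set.seed(42)
  for (rr in random_rotation(5)) {
    moved <- rigid_transform(ion, rr, c(3, -2, 7))
    expect_equal(pair_distances(moved), pair_distances(ion),
                 tolerance = 1e-9)
    expect_equal(moved$atoms$partial_charge, ion$atoms$partial_charge)
    expect_equal(moved$mass, ion$mass)
  }
  expect_error(rigid_transform(ion, diag(3) * 1.01), "orthonormal")
})

test_that("MOBCAL-style record export writes one line per atom", {
  f <- withr::local_tempfile()
  ion <- build_benzene()
  write_mobcal(ion, f)
  lines <- readLines(f)
  expect_equal(length(lines), 6 + nrow(ion$atoms))
  expect_equal(as.integer(lines[3]), 12)
})
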
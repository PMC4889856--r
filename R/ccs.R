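#' Sampling plan for the trajectory-method cross-section average
#'
#' The cross section is a triple average: uniform orientations on SO(3)
#' (uniform theta, gamma; cos-uniform phi, matching the sin-phi measure of
#' the orientation integral), a deterministic generalized Gauss-Laguerre
#' quadrature over relative speeds with the Maxwell-Boltzmann
#' `g^5 exp(-mu g^2 / 2 kB T)` weight, and stratified-antithetic sampling of
#' the impact parameter uniform in b^2 up to `b_max` (one mirrored pair per
#' stratum, which integrates anything linear in b^2 exactly and otherwise
#' reduces variance without bias). Orientations are split into `n_batches`
#' independent batches whose spread yields the Monte-Carlo standard error.
#'
#' @param n_orientations Number of ion orientations (total across batches).
#' @param n_velocity_points Gauss-Laguerre nodes for the speed integral.
#' @param n_impact_samples Impact-parameter strata (each contributes an
#'   antithetic pair of trajectories).
#' @param seed RNG seed; identical plans give bit-identical results.
#' @param b_max Impact-parameter cutoff in Angstrom, or `NULL` to determine
#'   it with [choose_bmax()].
#' @param n_batches Batches for the standard-error estimate.
#' @return A `sampling_plan` list.
#' @export
sampling_plan <- function(n_orientations = 250, n_velocity_points = 16,
                          n_impact_samples = 40, seed = 1L, b_max = NULL,
                          n_batches = 10) {
  stopifnot(n_orientations >= 1, n_velocity_points >= 1,
            n_impact_samples >= 1, n_batches >= 1,
            n_batches <= n_orientations, is.null(b_max) || b_max > 0)
  structure(list(n_orientations = as.integer(n_orientations),
                 n_velocity_points = as.integer(n_velocity_points),
                 n_impact_samples = as.integer(n_impact_samples),
                 seed = as.integer(seed), b_max = b_max,
                 n_batches = as.integer(n_batches)),
            class = "sampling_plan")
}

#' Gauss-Laguerre quadrature for the Maxwell-Boltzmann speed average
#'
#' Nodes and weights for averaging a cross section over the relative-speed
#' distribution proportional to `g^5 exp(-mu g^2 / 2 kB T)`. Substituting
#' `t = mu g^2 / 2 kB T` maps the integral onto the generalized
#' Gauss-Laguerre weight `t^2 e^-t` (whose total mass is Gamma(3) = 2, the
#' closed form of the g^5 integral used for normalization), so the returned
#' weights sum to 1 and a constant cross section is reproduced exactly.
#' Nodes scale as sqrt(T/mu).
#'
#' @param temperature Temperature, K.
#' @param mu Reduced mass, Da.
#' @param n_points Number of nodes.
#' @return A tibble with columns `g` (Angstrom/ps) and `weight`.
#' @export
velocity_quadrature <- function(temperature, mu, n_points = 16) {
  stopifnot(temperature > 0, mu > 0, n_points >= 1)
  gl <- pracma::gaussLaguerre(n_points, 2)
  kT <- physical_constants()$k_B_meV * temperature          # meV
  g <- sqrt(2 * kT * 9.64853329 * gl$x / mu)                # A/ps
  tibble::tibble(g = g, weight = gl$w / 2)
}

# deterministic low-discrepancy orientation set (golden-angle in theta/gamma,
# stratified cos-phi); used where an orientation probe must not touch the
# R RNG stream
.probe_rotations <- function(k) {
  ga <- pi * (3 - sqrt(5))
  lapply(seq_len(k), function(i) {
    euler_rotation(theta = (i * ga) %% (2 * pi),
                   phi = acos(1 - 2 * (i - 0.5) / k),
                   gamma = (i * ga * 2) %% (2 * pi))
  })
}

#' Impact-parameter cutoff for the cross-section integral
#'
#' The impact-parameter integral formally extends to infinity; this finds
#' the smallest b at which the largest deflection over a deterministic probe
#' set of orientations falls below 1e-3 rad (evaluated at a low-side thermal
#' speed `sqrt(2 kB T / mu)`, where deflections are largest among
#' appreciably weighted speeds), then applies a safety factor of 1.2.
#'
#' @param ion A [molecular_ion()].
#' @param gas A [drift_gas()].
#' @param temperature Temperature, K.
#' @param n_probe Orientations probed per b.
#' @param settings [integrator_settings()].
#' @return b_max in Angstrom.
#' @export
choose_bmax <- function(ion, gas, temperature = 298, n_probe = 6,
                        settings = integrator_settings()) {
  stopifnot(inherits(ion, "molecular_ion"), inherits(gas, "drift_gas"),
            temperature > 0)
  mu <- ion$mass * gas$mass / (ion$mass + gas$mass)
  kT <- physical_constants()$k_B_meV * temperature
  g_lo <- sqrt(2 * kT * 9.64853329 / mu)
  lj <- .lj_for_ion(ion, gas)
  rots <- .probe_rotations(n_probe)
  coords <- lapply(rots, function(r) ion_coords(ion) %*% t(r))
  max_chi <- function(b) {
    chis <- vapply(coords, function(cm) {
      out <- cpp_scatter(cm, ion$atoms$partial_charge, lj$epsilon, lj$sigma,
                         .gas_cpp(gas), c(0, 0, 1), mu, b, g_lo, settings)
      if (out$status >= 1) pi else abs(out$chi)
    }, 0)
    max(chis)
  }
  r_ext <- sqrt(max(rowSums(ion_coords(ion)^2)))
  b <- max(r_ext + 2, 4)
  while (max_chi(b) >= 1e-3) {
    b <- b + 2
    if (b > 100) {
      stop("b_max search did not converge within 100 Angstrom", call. = FALSE)
    }
  }
  lo <- max(b - 2, 0.1)
  for (i in 1:6) {  # bisect to ~0.03 A
    mid <- (lo + b) / 2
    if (max_chi(mid) >= 1e-3) lo <- mid else b <- mid
  }
  1.2 * b
}

#' Trajectory-method collision cross section
#'
#' Momentum-transfer collision cross section of a molecular ion in a drift
#' gas: the average of `integral 2 pi b (1 - cos chi) db` over ion
#' orientations and Maxwell-Boltzmann-weighted relative speeds, with the
#' scattering angle chi obtained from classical trajectories in the
#' Lennard-Jones + ion-induced-dipole (+ optional ion-quadrupole)
#' potential. The normalization is anchored by the hard-sphere limit: a
#' hard-sphere deflection function of diameter d returns exactly pi d^2.
#'
#' Trapped orbits (possible in the attractive r^-4 tail) are counted; each
#' contributes its isotropic-scattering expectation `1 - cos chi = 1`. If
#' more than 1% of trajectories are trapped the run aborts. If the
#' deflection at `b_max` is still above 1e-3 rad, a warning is recorded in
#' the result rather than silently accepted.
#'
#' @param ion A [molecular_ion()].
#' @param gas A [drift_gas()].
#' @param temperature Temperature, K.
#' @param plan A [sampling_plan()].
#' @param settings [integrator_settings()].
#' @param chi_fun Optional deflection-function plug-in, vectorized over
#'   `(b, g)` and returning chi in radians. Replaces trajectory integration;
#'   used for analytic anchors (hard sphere) and oracle cross-checks.
#' @return A `ccs_result`: `omega` (Angstrom^2), `stderr` (between-batch
#'   Monte-Carlo standard error), `temperature`, `trapped_fraction`,
#'   `n_trajectories`, `warnings` and the echoed `plan` (with the realized
#'   `b_max`).
#' @examples
#' \donttest{
#' plan <- sampling_plan(24, 6, 12, seed = 7)
#' compute_ccs(build_water_cluster(0), drift_gas("N2-iso"), 298, plan)
#' }
#' @export
compute_ccs <- function(ion, gas, temperature = 298, plan = sampling_plan(),
                        settings = integrator_settings(), chi_fun = NULL) {
  stopifnot(inherits(ion, "molecular_ion"), inherits(gas, "drift_gas"),
            inherits(plan, "sampling_plan"), temperature > 0)
  mu <- ion$mass * gas$mass / (ion$mass + gas$mass)
  vq <- velocity_quadrature(temperature, mu, plan$n_velocity_points)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(plan$seed)

  b_max <- plan$b_max
  if (is.null(b_max)) b_max <- choose_bmax(ion, gas, temperature,
                                           settings = settings)
  plan$b_max <- b_max

  n_or <- plan$n_orientations
  n_imp <- plan$n_impact_samples
  n_vel <- plan$n_velocity_points
  batch_id <- rep(seq_len(plan$n_batches), length.out = n_or)
  # orientations: uniform theta/gamma, cos-uniform phi
  theta <- stats::runif(n_or, 0, 2 * pi)
  phi <- acos(stats::runif(n_or, -1, 1))
  gamma <- stats::runif(n_or, 0, 2 * pi)
  # strata in u = b^2 with boundaries uniform in b (quadratic stretch), so
  # the strongly deflecting core is resolved by many strata while the soft
  # large-b tail gets wide ones; stratum means are width-weighted, which
  # stays unbiased and keeps linear-in-b^2 integrands exact
  bounds <- b_max^2 * (seq(0, n_imp) / n_imp)^2
  width <- diff(bounds)
  centers <- (bounds[-1] + bounds[-(n_imp + 1)]) / 2
  # one antithetic offset per (orientation, g-node, stratum)
  delta <- array(stats::runif(n_or * n_vel * n_imp, -0.5, 0.5),
                 c(n_or, n_vel, n_imp)) *
    rep(width, each = n_or * n_vel)
  # frozen gas axis per (orientation, stratum, pair): isotropic
  multi <- nrow(gas$sites) > 1
  n_jobs_per_or <- n_vel * n_imp * 2
  axis_all <- if (multi) {
    z <- stats::runif(n_or * n_jobs_per_or, -1, 1)
    a <- stats::runif(n_or * n_jobs_per_or, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    cbind(s * cos(a), s * sin(a), z)
  } else {
    matrix(rep(c(0, 0, 1), each = n_or * n_jobs_per_or), ncol = 3)
  }

  # job table: orientation index, g, b (antithetic pair per stratum)
  jobs <- tibble::tibble(
    orient = rep(seq_len(n_or), each = n_jobs_per_or),
    gi = rep(rep(seq_len(n_vel), each = n_imp * 2), times = n_or),
    stratum = rep(rep(seq_len(n_imp), times = 2 * n_vel), times = n_or)
  )
  jobs$g <- vq$g[jobs$gi]
  jobs$w <- vq$weight[jobs$gi]
  pair <- rep(rep(rep(c(1L, 2L), each = n_imp), times = n_vel), times = n_or)
  sgn <- ifelse(pair == 1L, 1, -1)
  u <- centers[jobs$stratum] +
    sgn * delta[cbind(jobs$orient, jobs$gi, jobs$stratum)]
  jobs$b <- sqrt(u)

  warnings <- character()
  if (!is.null(chi_fun)) {
    chi <- chi_fun(jobs$b, jobs$g)
    one_minus_cos <- 1 - cos(chi)
    trapped_fraction <- 0
  } else {
    lj <- .lj_for_ion(ion, gas)
    rots <- purrr::pmap(list(theta, phi, gamma), euler_rotation)
    coords <- lapply(rots, function(r) ion_coords(ion) %*% t(r))
    res <- cpp_scatter_batch(coords, ion$atoms$partial_charge, lj$epsilon,
                             lj$sigma, .gas_cpp(gas), mu, jobs$orient,
                             jobs$g, jobs$b, axis_all, settings)
    if (any(res$status == 3L)) {
      stop("near-singularity encountered during trajectory integration",
           call. = FALSE)
    }
    if (any(res$status == 2L)) {
      stop(sprintf(
        "%d trajectories failed energy conservation (drift > %g after retries)",
        sum(res$status == 2L), settings$energy_tol), call. = FALSE)
    }
    trapped <- res$status == 1L
    trapped_fraction <- mean(trapped)
    if (trapped_fraction > 0.01) {
      stop(sprintf(
        "trapped-orbit fraction %.2f%% exceeds 1%%; enlarge max_steps or revisit the potential",
        100 * trapped_fraction), call. = FALSE)
    }
    one_minus_cos <- 1 - cos(res$chi)
    one_minus_cos[trapped] <- 1  # isotropic expectation for trapped orbits
    # b_max adequacy: deterministic probe at b_max
    probe <- cpp_scatter(coords[[1]], ion$atoms$partial_charge, lj$epsilon,
                         lj$sigma, .gas_cpp(gas), c(0, 0, 1), mu, b_max,
                         stats::median(vq$g), settings)
    if (probe$status == 0 && abs(probe$chi) >= 1e-3) {
      warnings <- c(warnings, sprintf(
        "deflection at b_max = %.2f A is %.2e rad (>= 1e-3): b_max may be too small",
        b_max, abs(probe$chi)))
    }
  }

  # per-orientation cross section:
  # pi sum_g w_g sum_strata width_j mean_pair(1 - cos chi)
  per_or <- tibble::tibble(orient = jobs$orient,
                           w = jobs$w * width[jobs$stratum] / 2,
                           v = one_minus_cos) |>
    dplyr::group_by(.data$orient) |>
    dplyr::summarise(omega = pi * sum(.data$w * .data$v), .groups = "drop")
  per_or$batch <- batch_id[per_or$orient]
  batch_omega <- per_or |>
    dplyr::group_by(.data$batch) |>
    dplyr::summarise(omega = mean(.data$omega), .groups = "drop")
  omega <- mean(batch_omega$omega)
  stderr <- if (plan$n_batches > 1) {
    stats::sd(batch_omega$omega) / sqrt(plan$n_batches)
  } else 0
  structure(
    list(ion = ion$name, gas = gas$name, omega = omega, stderr = stderr,
         temperature = temperature, trapped_fraction = trapped_fraction,
         n_trajectories = nrow(jobs), plan = plan, warnings = warnings),
    class = "ccs_result"
  )
}

#' @export
print.ccs_result <- function(x, ...) {
  cat(sprintf(
    "<ccs_result> %s in %s at %.1f K: omega = %.2f +/- %.2f A^2 (%d trajectories, trapped %.2f%%)\n",
    x$ion, x$gas, x$temperature, x$omega, x$stderr, x$n_trajectories,
    100 * x$trapped_fraction))
  for (w in x$warnings) cat(" warning:", w, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname compute_ccs
#' @param x A `ccs_result`.
#' @param ... Unused.
#' @export
tidy.ccs_result <- function(x, ...) {
  tibble::tibble(ion = x$ion, gas = x$gas, temperature = x$temperature,
                 omega = x$omega, stderr = x$stderr,
                 trapped_fraction = x$trapped_fraction,
                 n_trajectories = x$n_trajectories)
}

#' @rdname compute_ccs
#' @export
glance.ccs_result <- function(x, ...) {
  tibble::tibble(omega = x$omega, stderr = x$stderr,
                 b_max = x$plan$b_max, seed = x$plan$seed,
                 n_orientations = x$plan$n_orientations,
                 n_velocity_points = x$plan$n_velocity_points,
                 n_impact_samples = x$plan$n_impact_samples,
                 n_warnings = length(x$warnings))
}

#' Serialize a cross-section result to JSON
#'
#' Writes omega, stderr, the full sampling plan (seed included) and the gas
#' parameter provenance, so a run can be reproduced exactly.
#'
#' @param result A `ccs_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
ccs_to_json <- function(result, path) {
  stopifnot(inherits(result, "ccs_result"))
  obj <- unclass(result)
  obj$ion <- result$ion
  obj$plan <- unclass(result$plan)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Orientation-averaged hard-sphere projection cross section
#'
#' Cheap geometric reference: each atom is a hard disc of radius `sigma`
#' (its LJ diameter against the gas) and the cross section is the average
#' projected shadow area over orientations. This is the fast
#' projection-approximation estimate used here only as an independent
#' sanity check of molecular size orderings, not as a substitute for the
#' trajectory average.
#'
#' @param ion A [molecular_ion()].
#' @param gas A [drift_gas()].
#' @param n_orientations Orientations averaged (deterministic set).
#' @param n_grid Monte-Carlo points per orientation.
#' @param seed RNG seed.
#' @return Cross section in Angstrom^2.
#' @export
ccs_projection <- function(ion, gas, n_orientations = 64, n_grid = 4000,
                           seed = 1L) {
  lj <- .lj_for_ion(ion, gas)
  xyz <- ion_coords(ion)
  rad <- lj$sigma
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rots <- .probe_rotations(n_orientations)
  areas <- vapply(rots, function(r) {
    p <- xyz %*% t(r)
    lim <- c(min(p[, 1] - rad), max(p[, 1] + rad),
             min(p[, 2] - rad), max(p[, 2] + rad))
    px <- stats::runif(n_grid, lim[1], lim[2])
    py <- stats::runif(n_grid, lim[3], lim[4])
    hit <- rep(FALSE, n_grid)
    for (i in seq_len(nrow(p))) {
      hit <- hit | ((px - p[i, 1])^2 + (py - p[i, 2])^2 <= rad[i]^2)
    }
    mean(hit) * (lim[2] - lim[1]) * (lim[4] - lim[3])
  }, 0)
  mean(areas)
}

#' Batch cross sections from a manifest of structure files
#'
#' Reads a manifest CSV with columns `name` and `path` (paths to
#' [read_xyzq()] files, relative paths resolved against the manifest's
#' directory), computes the trajectory-method cross section for each and
#' returns one tidy row per ion.
#'
#' @param manifest Path to the manifest CSV.
#' @param gas A [drift_gas()].
#' @param temperature Temperature, K.
#' @param plan A [sampling_plan()].
#' @param settings [integrator_settings()].
#' @return A tibble with columns `name`, `mass`, `omega`, `stderr`,
#'   `trapped_fraction`.
#' @export
ccs_batch <- function(manifest, gas = drift_gas("N2-iso"), temperature = 298,
                      plan = sampling_plan(), settings = integrator_settings()) {
  man <- utils::read.csv(manifest, comment.char = "#",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("name", "path") %in% names(man)))
  root <- dirname(manifest)
  purrr::pmap_dfr(man[, c("name", "path")], function(name, path) {
    if (!file.exists(path)) path <- file.path(root, path)
    ion <- read_xyzq(path)
    res <- compute_ccs(ion, gas, temperature, plan, settings)
    tibble::tibble(name = name, mass = ion$mass, omega = res$omega,
                   stderr = res$stderr,
                   trapped_fraction = res$trapped_fraction)
  })
}
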
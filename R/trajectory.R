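#' Integrator settings for scattering trajectories
#'
#' The probe state (position + velocity of the equivalent one-body particle
#' of reduced mass mu) is advanced with an adaptive 4th/5th-order
#' Runge-Kutta (Cash-Karp) scheme. A trajectory is accepted only if total
#' energy is conserved to `energy_tol` (relative to the asymptotic kinetic
#' energy); on violation the local error tolerance is tightened tenfold and
#' the trajectory re-integrated, up to `max_retries` times. Start and stop
#' radii are chosen per trajectory so that `|V| <= start_vfrac` times the
#' kinetic energy, bounding the truncation of the asymptotic regions.
#'
#' @param rtol Relative local error tolerance per step.
#' @param atol Absolute local error floor (Angstrom / Angstrom-per-ps).
#' @param energy_tol Maximum relative total-energy drift on acceptance.
#' @param init_dt Initial time step, ps (also capped at 0.5 A of travel).
#' @param start_vfrac Potential-to-kinetic-energy ratio defining the
#'   asymptotic start/stop radius.
#' @param max_steps Step cap; exceeding it classifies the trajectory as a
#'   trapped orbit.
#' @param max_retries Tolerance-tightening retries on energy-drift failure.
#' @return A list of settings.
#' @export
integrator_settings <- function(rtol = 1e-5, atol = 1e-8, energy_tol = 1e-3,
                                init_dt = 0.1, start_vfrac = 1e-3,
                                max_steps = 50000L, max_retries = 3L) {
  stopifnot(rtol > 0, atol > 0, energy_tol > 0, init_dt > 0,
            start_vfrac > 0, max_steps >= 1, max_retries >= 0)
  list(rtol = rtol, atol = atol, energy_tol = energy_tol, init_dt = init_dt,
       start_vfrac = start_vfrac, max_steps = as.integer(max_steps),
       max_retries = as.integer(max_retries))
}

#' Integrate one collision trajectory and extract the scattering angle
#'
#' Launches the drift-gas probe with relative speed `g` at impact parameter
#' `b` against the rigid ion (rotated into the collision frame by the Euler
#' angles), integrates through the interaction region, and returns the
#' scattering angle chi between the asymptotic incoming and outgoing
#' velocity directions.
#'
#' @param ion A [molecular_ion()].
#' @param gas A [drift_gas()].
#' @param b Impact parameter, Angstrom (>= 0).
#' @param g Relative speed, Angstrom/ps (> 0).
#' @param orientation Euler angles `c(theta, phi, gamma)` (z-y-z) rotating
#'   the ion into the collision geometry.
#' @param gas_axis Frozen orientation axis of a multi-site gas.
#' @param settings [integrator_settings()].
#' @return A `trajectory_result`: list with `chi` (rad), `energy_drift`
#'   (relative), `steps`, `trapped` (logical) and the final `pos`/`vel`
#'   of the probe. Head-on collisions with a repulsive core give
#'   `chi = pi`; distant misses give `chi ~ 0`.
#' @examples
#' \donttest{
#' res <- scatter(build_water_cluster(0), drift_gas("N2-iso"), b = 2, g = 6)
#' res$chi
#' }
#' @export
scatter <- function(ion, gas, b, g, orientation = c(0, 0, 0),
                    gas_axis = c(0, 0, 1), settings = integrator_settings()) {
  stopifnot(inherits(ion, "molecular_ion"), inherits(gas, "drift_gas"),
            b >= 0, g > 0)
  rot <- euler_rotation(orientation[1], orientation[2], orientation[3])
  rotated <- rigid_transform(ion, rot)
  lj <- .lj_for_ion(ion, gas)
  mu <- ion$mass * gas$mass / (ion$mass + gas$mass)
  nrm <- sqrt(sum(gas_axis^2))
  out <- cpp_scatter(ion_coords(rotated), ion$atoms$partial_charge,
                     lj$epsilon, lj$sigma, .gas_cpp(gas),
                     as.numeric(gas_axis / nrm), mu, b, g, settings)
  if (out$status == 3) {
    stop("near-singularity encountered along the trajectory", call. = FALSE)
  }
  if (out$status == 2) {
    stop(sprintf(
      "energy not conserved (relative drift %.2e > %.1e) after %d tolerance retries",
      out$energy_drift, settings$energy_tol, settings$max_retries
    ), call. = FALSE)
  }
  structure(
    list(chi = out$chi, energy_drift = out$energy_drift, steps = out$steps,
         trapped = out$status == 1L, pos = out$pos, vel = out$vel,
         b = b, g = g),
    class = "trajectory_result"
  )
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf(
    "<trajectory_result> chi = %.4f rad, energy drift %.1e, %d steps%s\n",
    x$chi, x$energy_drift, x$steps, if (x$trapped) " [trapped]" else ""))
  invisible(x)
}

#' Classical deflection angle of a central potential (quadrature oracle)
#'
#' Independent closed-form route to the scattering angle for spherically
#' symmetric potentials: chi = pi - 2 b * integral over r from the turning
#' point of dr / (r^2 sqrt(1 - b^2/r^2 - V(r)/E)). The outermost turning
#' point is located by sign-change bracketing and the integrable endpoint
#' singularity removed by the substitution 1/r = s0 sin(t). Used to validate
#' the trajectory integrator on central potentials; it shares no code with
#' it.
#'
#' @param V_fun Vectorized radial potential V(r), meV.
#' @param b Impact parameter, Angstrom.
#' @param g Relative speed, Angstrom/ps.
#' @param mu Reduced mass, Da.
#' @param r_max Outer radius from which the turning-point scan starts.
#' @return Deflection angle chi in radians (0 for zero potential; positive
#'   for net repulsion, negative for net attraction).
#' @export
deflection_integral_oracle <- function(V_fun, b, g, mu, r_max = 300) {
  stopifnot(b >= 0, g > 0, mu > 0)
  E <- 0.5 * mu * g^2 / 9.64853329  # kinetic energy, meV
  f <- function(r) 1 - (b / r)^2 - V_fun(r) / E
  if (b == 0) {
    # head-on: chi is pi for a repulsive core by symmetry
    f <- function(r) 1 - V_fun(r) / E
  }
  # outermost turning point: scan inward on a log grid for the sign change
  rs <- exp(seq(log(r_max), log(0.05), length.out = 4000))
  fv <- f(rs)
  idx <- which(fv <= 0)[1]
  if (is.na(idx) || idx == 1L) {
    if (b == 0) return(pi)  # purely repulsive head-on limit
    stop("no turning point found: potential never stops the radial motion",
         call. = FALSE)
  }
  r0 <- stats::uniroot(f, c(rs[idx], rs[idx - 1]), tol = 1e-13)$root
  s0 <- 1 / r0
  integrand <- function(t) {
    s <- s0 * sin(t)
    Fv <- 1 - (b * s)^2 - V_fun(1 / s) / E
    b * s0 * cos(t) / sqrt(pmax(Fv, 1e-14))
  }
  val <- stats::integrate(integrand, 0, pi / 2, rel.tol = 1e-9,
                          subdivisions = 400L)$value
  pi - 2 * val
}
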
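#' Drift conditions
#'
#' @param temperature Temperature, K.
#' @param number_density Drift-gas number density, cm^-3. Defaults to the
#'   ideal-gas density at `temperature` and 101325 Pa.
#' @param composition Named mole fractions of the drift gas (must sum to 1).
#' @return A `conditions` list.
#' @export
conditions <- function(temperature = 298.15, number_density = NULL,
                       composition = c(N2 = 1)) {
  stopifnot(temperature > 0)
  if (is.null(number_density)) {
    pc <- physical_constants()
    number_density <- 101325 / (pc$k_B * temperature) * 1e-6
  }
  stopifnot(number_density > 0)
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("gas mole fractions must sum to 1", call. = FALSE)
  }
  structure(list(temperature = temperature, number_density = number_density,
                 composition = composition),
            class = "conditions")
}

#' Drift-tube geometry
#'
#' @param L Drift length, cm.
#' @param U Voltage drop over the full drift length, V.
#' @return An `instrument_geometry` list.
#' @export
instrument_geometry <- function(L = 5.5, U = 1925) {
  stopifnot(L > 0, U > 0)
  structure(list(L = L, U = U), class = "instrument_geometry")
}

# CRC-style gas constants at standard conditions; the dielectric constants
# enter the Langevin polarization-limit correction through (D - 1), which is
# proportional to the gas polarizability
.gas_properties_table <- tibble::tibble(
  name = c("N2", "O2"),
  mass = c(28.014, 31.998),          # Da
  dielectric = c(1.000548, 1.000495) # at 1 atm, ~293 K
)

#' Bulk gas properties for mobility conversions
#'
#' @param name `"N2"` or `"O2"`, or a row can be overridden by passing
#'   `mass` and `dielectric` directly.
#' @param mass Molecular mass, Da.
#' @param dielectric Relative dielectric constant (> 1).
#' @return A `gas_properties` list.
#' @export
gas_properties <- function(name, mass = NULL, dielectric = NULL) {
  if (is.null(mass) || is.null(dielectric)) {
    row <- .gas_properties_table[.gas_properties_table$name == name, ]
    if (nrow(row) != 1) {
      stop("unknown gas '", name,
           "'; supply mass and dielectric explicitly", call. = FALSE)
    }
    if (is.null(mass)) mass <- row$mass
    if (is.null(dielectric)) dielectric <- row$dielectric
  }
  if (dielectric <= 1) stop("dielectric constant must exceed 1", call. = FALSE)
  stopifnot(mass > 0)
  structure(list(name = name, mass = mass, dielectric = dielectric),
            class = "gas_properties")
}

.new_mobility <- function(K, cond) {
  pc <- physical_constants()
  structure(list(K = K, K0 = K * cond$number_density / pc$loschmidt,
                 conditions = cond),
            class = "mobility_value")
}

#' @export
print.mobility_value <- function(x, ...) {
  cat(sprintf(
    "<mobility_value> K = %.4f cm^2 V^-1 s^-1 (K0 = %.4f) at %.2f K, N = %.4g cm^-3 [%s]\n",
    x$K, x$K0, x$conditions$temperature, x$conditions$number_density,
    paste(sprintf("%s:%.2f", names(x$conditions$composition),
                  x$conditions$composition), collapse = " ")))
  invisible(x)
}

.K_of <- function(x) if (inherits(x, "mobility_value")) x$K else as.numeric(x)

#' Mason-Schamp mobility from a collision cross section
#'
#' Low-field ion mobility
#' `K = (3/16) (q/N) sqrt(1/M + 1/m) sqrt(2 pi / (kB T)) / omega`,
#' evaluated in SI internally and returned in the customary
#' cm^2 V^-1 s^-1. The reduced mobility `K0` rescales `K` to the standard
#' number density (273.15 K, 101325 Pa), so it is independent of the
#' operating (T, N) for a fixed cross section.
#'
#' @param omega Collision cross section, Angstrom^2 (or a `ccs_result`).
#' @param m Analyte ion mass, Da.
#' @param M Drift-gas molecular mass, Da.
#' @param q Ion charge, integer elementary charges.
#' @param temperature Temperature, K.
#' @param number_density Gas number density, cm^-3 (default: 101325 Pa at
#'   `temperature`).
#' @param composition Named mole fractions describing the gas.
#' @return A `mobility_value` with `K`, `K0` and the conditions.
#' @examples
#' mason_schamp(100, m = 91, M = 28.014, temperature = 298)
#' @export
mason_schamp <- function(omega, m, M, q = 1L, temperature = 298.15,
                         number_density = NULL, composition = c(N2 = 1)) {
  if (inherits(omega, "ccs_result")) {
    temperature <- omega$temperature
    omega <- omega$omega
  }
  if (any(c(omega, m, M, q, temperature) <= 0)) {
    stop("omega, masses, charge and temperature must all be positive",
         call. = FALSE)
  }
  cond <- conditions(temperature, number_density, composition)
  pc <- physical_constants()
  mu_kg <- (m * M / (m + M)) * pc$amu
  omega_m2 <- omega * 1e-20
  N_m3 <- cond$number_density * 1e6
  K_si <- (3 / 16) * (q * pc$e_charge / N_m3) *
    sqrt(2 * pi / (mu_kg * pc$k_B * temperature)) / omega_m2
  .new_mobility(K_si * 1e4, cond)
}

#' A measured drift peak
#'
#' @param drift_time Drift time, ms (> 0).
#' @param intensity Peak intensity, arbitrary units.
#' @return A `measured_peak` list.
#' @export
measured_peak <- function(drift_time, intensity = 1) {
  stopifnot(drift_time > 0)
  structure(list(drift_time = drift_time, intensity = intensity),
            class = "measured_peak")
}

#' Mobility from a drift-time measurement
#'
#' `K = L^2 / (t_D U)`: the mobility directly available from flight-time
#' measurements in a drift tube of length `L` with total voltage drop `U`.
#'
#' @param geometry An [instrument_geometry()].
#' @param peak A [measured_peak()] or a drift time in ms.
#' @param conditions_ A [conditions()] attached to the returned value.
#' @return A `mobility_value` in cm^2 V^-1 s^-1.
#' @examples
#' mobility_from_drift(instrument_geometry(5.5, 1925), measured_peak(6))
#' @export
mobility_from_drift <- function(geometry, peak,
                                conditions_ = conditions()) {
  stopifnot(inherits(geometry, "instrument_geometry"))
  t_ms <- if (inherits(peak, "measured_peak")) peak$drift_time else peak
  if (!is.numeric(t_ms) || t_ms <= 0) {
    stop("drift time must be positive", call. = FALSE)
  }
  K <- geometry$L^2 / ((t_ms / 1000) * geometry$U)
  .new_mobility(K, conditions_)
}

#' Drift time from a mobility (inverse of Eq. 3-style conversion)
#'
#' @param geometry An [instrument_geometry()].
#' @param K Mobility in cm^2 V^-1 s^-1 (or a `mobility_value`).
#' @return Drift time in ms.
#' @export
drift_from_mobility <- function(geometry, K) {
  stopifnot(inherits(geometry, "instrument_geometry"))
  K <- .K_of(K)
  stopifnot(K > 0)
  geometry$L^2 / (K * geometry$U) * 1000
}

#' Langevin polarization-limit correction from nitrogen to oxygen
#'
#' In the polarization (Langevin) limit the mobility depends on the gas only
#' through `1 / sqrt(alpha mu)`, with the polarizability proportional to
#' `(D - 1)` of the dielectric constant. The oxygen mobility therefore
#' follows from the nitrogen one as
#' `K_O2 = K_N2 sqrt((D_N2 - 1) M_N2 (m + M_O2) / ((D_O2 - 1) M_O2 (m + M_N2)))`.
#' The correction is small (a few percent) for the analyte masses handled
#' here, which is what justifies using calculated nitrogen mobilities for
#' measurements in air.
#'
#' @param K_n2 Mobility in nitrogen, cm^2 V^-1 s^-1 (or a `mobility_value`).
#' @param m Analyte ion mass, Da.
#' @param props A list with elements `n2` and `o2`, each a
#'   [gas_properties()].
#' @return The oxygen mobility, same type as `K_n2`.
#' @export
o2_from_n2 <- function(K_n2, m, props = list(n2 = gas_properties("N2"),
                                             o2 = gas_properties("O2"))) {
  stopifnot(m > 0)
  n2 <- props$n2; o2 <- props$o2
  if (n2$dielectric <= 1 || o2$dielectric <= 1) {
    stop("dielectric constants must exceed 1", call. = FALSE)
  }
  ratio <- sqrt(((n2$dielectric - 1) * n2$mass * (m + o2$mass)) /
                ((o2$dielectric - 1) * o2$mass * (m + n2$mass)))
  if (inherits(K_n2, "mobility_value")) {
    cond <- K_n2$conditions
    cond$composition <- c(O2 = 1)
    out <- .new_mobility(K_n2$K * ratio, cond)
    out
  } else {
    K_n2 * ratio
  }
}

#' Blanc's-law mobility of a gas mixture
#'
#' Harmonic mole-fraction mixing: `1/K_mix = sum_i x_i / K_i`. The mixture
#' mobility always lies between the smallest and largest component
#' mobilities.
#'
#' @param K Numeric vector of component mobilities (or list of
#'   `mobility_value`s), cm^2 V^-1 s^-1.
#' @param fractions Mole fractions, summing to 1.
#' @return Mixture mobility as a plain number, or a `mobility_value` if the
#'   first component was one.
#' @examples
#' blanc_mix(c(2.0, 1.9), c(0.79, 0.21))
#' @export
blanc_mix <- function(K, fractions) {
  if (length(K) == 0) stop("no components given", call. = FALSE)
  Kv <- vapply(as.list(K), .K_of, 0)
  if (length(fractions) != length(Kv)) {
    stop("one mole fraction per component is required", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("mole fractions must sum to 1", call. = FALSE)
  }
  if (any(Kv <= 0) || any(fractions < 0)) {
    stop("mobilities must be positive and fractions non-negative",
         call. = FALSE)
  }
  Kmix <- 1 / sum(fractions / Kv)
  first <- if (is.list(K)) K[[1]] else K[1]
  if (inherits(first, "mobility_value")) {
    cond <- first$conditions
    out <- .new_mobility(Kmix, cond)
    out
  } else {
    Kmix
  }
}

#' Mobility in ambient air from the nitrogen mobility
#'
#' Composes the Langevin-limit nitrogen-to-oxygen correction
#' ([o2_from_n2()]) with Blanc's-law mixing at the molar composition of air
#' (0.79 N2 / 0.21 O2, argon folded into the nitrogen fraction). For
#' analyte masses in the tens-to-hundreds of Da the air and nitrogen
#' mobilities differ by well under 3%.
#'
#' @inheritParams o2_from_n2
#' @param composition Named fractions for `N2` and `O2`.
#' @return The air mobility, same type as `K_n2`.
#' @examples
#' air_from_n2(2.0, m = 91)
#' @export
air_from_n2 <- function(K_n2, m, composition = c(N2 = 0.79, O2 = 0.21),
                        props = list(n2 = gas_properties("N2"),
                                     o2 = gas_properties("O2"))) {
  if (!setequal(names(composition), c("N2", "O2"))) {
    stop("composition must name N2 and O2 fractions", call. = FALSE)
  }
  K_o2 <- o2_from_n2(K_n2, m, props)
  Kmix <- blanc_mix(c(.K_of(K_n2), .K_of(K_o2)),
                    c(composition[["N2"]], composition[["O2"]]))
  if (inherits(K_n2, "mobility_value")) {
    cond <- K_n2$conditions
    cond$composition <- composition / sum(composition)
    .new_mobility(Kmix, cond)
  } else {
    Kmix
  }
}
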
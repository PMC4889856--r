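#' Physical constants (CODATA 2018)
#'
#' Fixed fundamental constants used throughout the package. All unit
#' conversions between the internal working units (length in Angstrom, mass
#' in Dalton, energy in meV, charge in elementary charges, time in ps) and SI
#' are centralized here; the list is locked so values cannot drift at run
#' time.
#'
#' @return A locked environment with elements:
#' \describe{
#'   \item{k_B}{Boltzmann constant, J/K.}
#'   \item{e_charge}{Elementary charge, C.}
#'   \item{amu}{Atomic mass unit, kg.}
#'   \item{loschmidt}{Number density of an ideal gas at 273.15 K and
#'     101325 Pa, cm^-3.}
#'   \item{k_B_meV}{Boltzmann constant, meV/K.}
#'   \item{coulomb_meV_A}{e^2/(4 pi eps0), in meV * Angstrom; prefactor of
#'     Coulomb energies between charges expressed in e and distances in
#'     Angstrom.}
#'   \item{meV_per_Da_A2_ps2}{Energy of 1 Da (Angstrom/ps)^2 expressed in
#'     meV; converts kinetic energies in internal units to meV.}
#' }
#' @examples
#' physical_constants()$k_B
#' @export
physical_constants <- function() .trajmob_constants

.make_constants <- function() {
  k_B <- 1.380649e-23        # J/K (exact)
  e_charge <- 1.602176634e-19 # C (exact)
  amu <- 1.66053906660e-27   # kg
  eps0 <- 8.8541878128e-12   # F/m
  # 1 Da * (A/ps)^2 in J: amu * (1e-10 m / 1e-12 s)^2 = amu * 1e4
  da_a2_ps2_J <- amu * 1e4
  env <- new.env(parent = emptyenv())
  env$k_B <- k_B
  env$e_charge <- e_charge
  env$amu <- amu
  env$loschmidt <- 101325 / (k_B * 273.15) * 1e-6  # cm^-3
  env$k_B_meV <- k_B / e_charge * 1e3              # meV/K
  env$coulomb_meV_A <- e_charge^2 / (4 * pi * eps0) / e_charge * 1e3 * 1e10
  env$meV_per_Da_A2_ps2 <- da_a2_ps2_J / (e_charge * 1e-3)
  lockEnvironment(env, bindings = TRUE)
  env
}

.trajmob_constants <- .make_constants()

# standard atomic weights (Da); nominal-mass work in this package rounds these
.atomic_weights <- c(
  H = 1.008, He = 4.0026, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Na = 22.990, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  Ar = 39.95, Br = 79.904, I = 126.904
)

#' Standard atomic weight of an element
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of atomic masses in Da.
#' @examples
#' atomic_mass(c("H", "O"))
#' @export
atomic_mass <- function(element) {
  m <- .atomic_weights[element]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("no tabulated atomic mass for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(m)
}
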
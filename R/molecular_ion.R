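#' Construct a molecular ion
#'
#' A molecular ion is an ordered table of atoms (element, Cartesian
#' coordinates in Angstrom, atomic mass in Da, partial charge in e) together
#' with its name and integer total charge. The per-atom partial charges carry
#' the charge distribution that the ion-induced-dipole and ion-quadrupole
#' parts of the interaction potential act on; they must sum to the total
#' charge within `charge_tolerance`.
#'
#' @param atoms A data frame with columns `element`, `x`, `y`, `z` and
#'   `partial_charge` (one row per atom, coordinates in Angstrom, charges in
#'   e). A `mass` column is added from the standard atomic weights if absent.
#' @param total_charge Integer net charge in elementary charges.
#' @param name Label for the ion.
#' @param charge_tolerance Maximum allowed |sum(partial charges) -
#'   total_charge|, in e. The default 0.01 e catches truncated charge tables
#'   without rejecting rounded quantum-chemical output.
#' @return An object of class `molecular_ion`: a list with elements `name`,
#'   `atoms` (a tibble), `total_charge` and `mass` (sum of atomic masses, Da).
#' @examples
#' hydronium <- build_water_cluster(0)
#' hydronium$mass
#' @export
molecular_ion <- function(atoms, total_charge, name = "ion",
                          charge_tolerance = 0.01) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("element", "x", "y", "z", "partial_charge")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) < 1) stop("a molecular ion needs at least one atom", call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  if (!all(is.finite(atoms$partial_charge))) {
    stop("partial charges must be finite", call. = FALSE)
  }
  if (!"mass" %in% names(atoms)) atoms$mass <- atomic_mass(atoms$element) else {
    if (any(atoms$mass <= 0)) stop("atom masses must be positive", call. = FALSE)
  }
  total_charge <- as.integer(total_charge)
  qsum <- sum(atoms$partial_charge)
  if (abs(qsum - total_charge) > charge_tolerance) {
    stop(sprintf(
      "partial charges sum to %+.4f e but total charge is %+d e (|diff| = %.4f > tolerance %.4f)",
      qsum, total_charge, abs(qsum - total_charge), charge_tolerance
    ), call. = FALSE)
  }
  structure(
    list(
      name = name,
      atoms = atoms[, c("element", "x", "y", "z", "mass", "partial_charge")],
      total_charge = total_charge,
      mass = sum(atoms$mass)
    ),
    class = "molecular_ion"
  )
}

#' @export
print.molecular_ion <- function(x, ...) {
  cat(sprintf("<molecular_ion> %s: %d atoms, mass %.3f Da, charge %+d e\n",
              x$name, nrow(x$atoms), x$mass, x$total_charge))
  print(x$atoms, n = 6)
  invisible(x)
}

#' @export
as_tibble.molecular_ion <- function(x, ...) x$atoms

#' Coordinates of a molecular ion as a matrix
#'
#' @param ion A `molecular_ion`.
#' @return An n x 3 numeric matrix of Cartesian coordinates in Angstrom.
#' @export
ion_coords <- function(ion) {
  stopifnot(inherits(ion, "molecular_ion"))
  as.matrix(ion$atoms[, c("x", "y", "z")])
}

#' Rigidly rotate and translate a molecular ion
#'
#' Applies `x' = R x + t` to every atom. The rotation must be orthonormal so
#' that all interatomic distances (and hence the physics) are preserved;
#' charges and masses are untouched.
#'
#' @param ion A `molecular_ion`.
#' @param rotation A 3 x 3 orthonormal matrix.
#' @param translation Length-3 numeric translation vector, Angstrom.
#' @return The transformed `molecular_ion`.
#' @examples
#' benz <- build_benzene()
#' rot <- diag(3)[c(2, 1, 3), ] * c(1, -1, 1)  # not orthonormal-checked here
#' moved <- rigid_transform(benz, diag(3), c(0, 0, 5))
#' @export
rigid_transform <- function(ion, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(ion, "molecular_ion"))
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-10) {
    stop("rotation must be a 3x3 orthonormal matrix (|R'R - I| <= 1e-10)",
         call. = FALSE)
  }
  if (length(translation) != 3 || !all(is.finite(translation))) {
    stop("translation must be a finite length-3 vector", call. = FALSE)
  }
  xyz <- ion_coords(ion) %*% t(rotation)
  out <- ion
  out$atoms$x <- xyz[, 1] + translation[1]
  out$atoms$y <- xyz[, 2] + translation[2]
  out$atoms$z <- xyz[, 3] + translation[3]
  out
}

#' Uniformly random rotation matrix
#'
#' Draws from the Haar measure on SO(3) (via quaternions), used for
#' orientation averaging. Consumes the R random number stream.
#'
#' @param n Number of rotations.
#' @return A list of 3 x 3 rotation matrices.
#' @export
random_rotation <- function(n = 1) {
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), nrow = 3, byrow = TRUE)
  })
}

#' Rotation matrix from Euler angles
#'
#' z-y-z convention: `R = Rz(theta) %*% Ry(phi) %*% Rz(gamma)`. Sampling
#' `theta`, `gamma` uniformly on `[0, 2*pi)` and `cos(phi)` uniformly on
#' `[-1, 1]` gives the uniform (sin-phi-weighted) orientation measure used in
#' the cross-section average.
#'
#' @param theta,phi,gamma Euler angles in radians.
#' @return A 3 x 3 rotation matrix.
#' @export
euler_rotation <- function(theta, phi, gamma) {
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                           3, 3, byrow = TRUE)
  rz(theta) %*% ry(phi) %*% rz(gamma)
}
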
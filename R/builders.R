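# Template geometry builders.
#
# These stand in for quantum-chemically optimized structures: bond lengths and
# angles are textbook idealizations (C-C 1.54 A, aromatic C-C 1.39 A, C-H
# 1.09 A, O-H 0.96-0.98 A, tetrahedral/trigonal angles), and the partial
# charges are fixed synthetic templates that sum exactly to the total charge.
# They give physically plausible sizes and charge distributions, not the
# specific geometries any one electronic-structure method would produce.

.unit <- function(v) v / sqrt(sum(v^2))

# orthonormal vector perpendicular to u
.any_perp <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(pracma::cross(u, ref))
}

# water molecule atoms: O at `origin`, H-H bisector along `axis` (H side),
# O-H 0.9572 A, H-O-H 104.5 deg; charges (qO, qH) with net qO + 2 qH
.water_atoms <- function(origin, axis, qO = -0.7, qH = 0.35) {
  axis <- .unit(axis)
  p <- .any_perp(axis)
  half <- 104.5 / 2 * pi / 180
  h1 <- origin + 0.9572 * (cos(half) * axis + sin(half) * p)
  h2 <- origin + 0.9572 * (cos(half) * axis - sin(half) * p)
  tibble::tibble(
    element = c("O", "H", "H"),
    x = c(origin[1], h1[1], h2[1]),
    y = c(origin[2], h1[2], h2[2]),
    z = c(origin[3], h1[3], h2[3]),
    partial_charge = c(qO, qH, qH)
  )
}

#' Build a protonated water cluster (H3O+)(H2O)n
#'
#' Template geometry for the reactant ions of positive-mode ion mobility
#' spectrometry: a pyramidal hydronium core (O-H 0.98 A, H-O-H ~111 deg)
#' with `n` waters placed at hydrogen-bonding distance (O-O 2.7-2.9 A) along
#' the three O-H directions, then the lone-pair axis and its antipode. The
#' packaged charge template puts +0.45 e on each hydronium H and -0.35 e on
#' its O (net +1); attached waters are neutral (O -0.70, H +0.35).
#'
#' @param n Number of attached waters, 0 to 5.
#' @return A [molecular_ion()] with `4 + 3 n` atoms and total charge +1.
#' @examples
#' build_water_cluster(4)$mass  # nominal mass 91 Da
#' @export
build_water_cluster <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 0) {
    stop("n must be a non-negative integer", call. = FALSE)
  }
  if (n > 5) stop("n must be at most 5", call. = FALSE)
  n <- as.integer(n)
  # hydronium: O at origin, lone-pair axis +z, H's below the xy-plane
  cosb <- -0.3077           # polar cosine giving H-O-H = 111 deg
  sinb <- sqrt(1 - cosb^2)
  psi <- c(0, 2, 4) * pi / 3
  hdir <- lapply(psi, function(a) c(sinb * cos(a), sinb * sin(a), cosb))
  hpos <- lapply(hdir, function(u) 0.98 * u)
  atoms <- tibble::tibble(
    element = c("O", "H", "H", "H"),
    x = c(0, vapply(hpos, `[`, 0, 1)),
    y = c(0, vapply(hpos, `[`, 0, 2)),
    z = c(0, vapply(hpos, `[`, 0, 3)),
    partial_charge = c(-0.35, 0.45, 0.45, 0.45)
  )
  sites <- c(hdir, list(c(0, 0, 1), c(0, 0, -1)))
  dists <- c(2.70, 2.70, 2.70, 2.90, 2.90)
  for (k in seq_len(n)) {
    o <- dists[k] * .unit(sites[[k]])
    atoms <- dplyr::bind_rows(atoms, .water_atoms(o, sites[[k]]))
  }
  molecular_ion(atoms, total_charge = 1L,
                name = sprintf("(H3O+)(H2O)%d", n))
}

.ring_atoms <- function(qC, qH) {
  ang <- (0:5) * pi / 3
  rc <- 1.39   # aromatic C-C
  rh <- rc + 1.09
  tibble::tibble(
    element = rep(c("C", "H"), each = 6),
    x = c(rc * cos(ang), rh * cos(ang)),
    y = c(rc * sin(ang), rh * sin(ang)),
    z = 0,
    partial_charge = rep(c(qC, qH), each = 6)
  )
}

#' Build a benzene or toluene radical cation
#'
#' Idealized planar ring (C-C 1.39 A, C-H 1.09 A); toluene replaces one ring
#' hydrogen by a methyl group (C-C 1.51 A, tetrahedral H). Total charge +1
#' reflects ionization by electron abstraction, the mechanism operative for
#' these aromatics at low humidity, rather than protonation. With
#' `with_water` a single neutral water is placed on the ring axis 3 A above
#' the centroid, bisector pointing away, emulating the post-ionization water
#' adduct.
#'
#' @param with_water Attach one water molecule above the ring centroid?
#' @return A [molecular_ion()] with total charge +1.
#' @examples
#' build_benzene()$mass          # ~78.11 Da
#' nrow(build_toluene(TRUE)$atoms)  # 18 atoms
#' @export
build_benzene <- function(with_water = FALSE) {
  qH <- 0.2
  atoms <- .ring_atoms(qC = 1 / 6 - qH, qH = qH)
  if (with_water) {
    atoms <- dplyr::bind_rows(atoms, .water_atoms(c(0, 0, 3.0), c(0, 0, 1)))
  }
  molecular_ion(atoms, total_charge = 1L,
                name = if (with_water) "(benzene)+(H2O)" else "(benzene)+")
}

#' @rdname build_benzene
#' @export
build_toluene <- function(with_water = FALSE) {
  qH <- 0.1
  qC <- (1 - 8 * qH) / 7
  atoms <- .ring_atoms(qC = qC, qH = qH)
  # replace the ring H at azimuth 0 (row 7) by a methyl carbon + 3 H
  w <- c(1, 0, 0)                       # radial axis of the C-CH3 bond
  cm <- (1.39 + 1.51) * w               # methyl C
  e1 <- c(0, 0, 1)
  e2 <- pracma::cross(w, e1)
  ct <- 1 / 3; st <- sqrt(1 - ct^2)     # tetrahedral: 109.47 deg from -w
  hm <- lapply(c(0, 2, 4) * pi / 3, function(a) {
    cm + 1.09 * (ct * w + st * (cos(a) * e1 + sin(a) * e2))
  })
  methyl <- tibble::tibble(
    element = c("C", "H", "H", "H"),
    x = c(cm[1], vapply(hm, `[`, 0, 1)),
    y = c(cm[2], vapply(hm, `[`, 0, 2)),
    z = c(cm[3], vapply(hm, `[`, 0, 3)),
    partial_charge = c(qC, qH, qH, qH)
  )
  atoms <- dplyr::bind_rows(atoms[-7, ], methyl)
  if (with_water) {
    atoms <- dplyr::bind_rows(atoms, .water_atoms(c(0, 0, 3.0), c(0, 0, 1)))
  }
  molecular_ion(atoms, total_charge = 1L,
                name = if (with_water) "(toluene)+(H2O)" else "(toluene)+")
}

#' Build an n-alkane radical cation, optionally with an attached water
#'
#' All-anti backbone (C-C 1.54 A, tetrahedral angles, C-H 1.09 A) for
#' CnH2n+2 with n between 6 and 10, ionized by electron abstraction (total
#' charge +1, spread uniformly over the alkane atoms as a synthetic stand-in
#' for a delocalized hole). With `with_water`, a neutral water oxygen sits
#' 3 A from the chain midpoint, perpendicular to the backbone plane — the
#' single-water adduct these charge-symmetric analytes form after
#' ionization.
#'
#' @param n_carbons Chain length, 6 to 10.
#' @param with_water Attach one water at the chain center?
#' @return A [molecular_ion()] with total charge +1.
#' @examples
#' build_alkane(6)$mass             # ~86.18 Da
#' nrow(build_alkane(10, TRUE)$atoms)  # 35 atoms
#' @export
build_alkane <- function(n_carbons, with_water = FALSE) {
  if (length(n_carbons) != 1 || is.na(n_carbons) ||
      n_carbons < 6 || n_carbons > 10) {
    stop("n_carbons must be between 6 and 10", call. = FALSE)
  }
  n <- as.integer(n_carbons)
  half <- acos(-1 / 3) / 2              # half the tetrahedral angle
  dx <- 1.54 * sin(half)
  dz <- 1.54 * cos(half)
  cpos <- lapply(seq_len(n), function(i) c((i - 1) * dx, 0, (i %% 2) * dz))
  hlen <- 1.09
  hpos <- list()
  for (i in seq_len(n)) {
    ci <- cpos[[i]]
    nb <- list()
    if (i > 1) nb <- c(nb, list(.unit(cpos[[i - 1]] - ci)))
    if (i < n) nb <- c(nb, list(.unit(cpos[[i + 1]] - ci)))
    if (length(nb) == 2) {
      u <- -.unit(nb[[1]] + nb[[2]])
      v <- .unit(pracma::cross(nb[[1]], nb[[2]]))
      hpos <- c(hpos, list(ci + hlen * (cos(half) * u + sin(half) * v),
                           ci + hlen * (cos(half) * u - sin(half) * v)))
    } else {
      # terminal CH3: three H at 109.47 deg from the single C-C bond
      a <- nb[[1]]
      w <- -a
      e1 <- .any_perp(w)
      e2 <- pracma::cross(w, e1)
      ct <- 1 / 3; st <- sqrt(1 - ct^2)
      # stagger the two chain ends differently
      off <- if (i == 1) pi / 6 else -pi / 6
      for (ak in c(0, 2, 4) * pi / 3 + off) {
        hpos <- c(hpos, list(ci + hlen * (ct * w + st * (cos(ak) * e1 +
                                                           sin(ak) * e2))))
      }
    }
  }
  n_atoms <- n + length(hpos)
  q <- 1 / n_atoms
  atoms <- tibble::tibble(
    element = c(rep("C", n), rep("H", length(hpos))),
    x = c(vapply(cpos, `[`, 0, 1), vapply(hpos, `[`, 0, 1)),
    y = c(vapply(cpos, `[`, 0, 2), vapply(hpos, `[`, 0, 2)),
    z = c(vapply(cpos, `[`, 0, 3), vapply(hpos, `[`, 0, 3)),
    partial_charge = q
  )
  if (with_water) {
    mid <- colMeans(do.call(rbind, cpos))
    o <- mid + c(0, 3.0, 0)
    atoms <- dplyr::bind_rows(atoms, .water_atoms(o, c(0, 1, 0)))
  }
  prefix <- c("hexane", "heptane", "octane", "nonane", "decane")[n - 5]
  molecular_ion(atoms, total_charge = 1L,
                name = if (with_water) paste0("(", prefix, ")+(H2O)")
                       else paste0("(", prefix, ")+"))
}
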
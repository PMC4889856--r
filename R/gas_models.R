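# Drift-gas models.
#
# The nitrogen model follows the N2-extended MOBCAL lineage: two
# Lennard-Jones sites on the N atoms (bond length 1.10 A), three point
# charges reproducing the N2 quadrupole moment (-0.4825 e on each N,
# +0.965 e at the bond center), and an isotropic polarizability acting at the
# molecular center. A cheaper single-site isotropic variant ("N2-iso": one
# LJ site, no quadrupole, same mass and polarizability) is the default for
# desk-scale cross-section runs. LJ well depths/diameters are stored per
# (ion element, gas) pair directly, the way MOBCAL-style tables are
# published; elements missing from the table raise an error rather than
# falling back to silent defaults.

.default_lj <- list(
  N2 = tibble::tibble(
    element = c("H", "C", "N", "O"),
    epsilon = c(1.34, 4.39, 4.60, 5.30),   # meV
    sigma   = c(2.38, 3.58, 3.60, 3.25)    # A
  )
)
.default_lj[["N2-iso"]] <- .default_lj$N2

#' Construct a drift-gas model
#'
#' @param name `"N2"` (two LJ sites + quadrupole charges) or `"N2-iso"`
#'   (single isotropic LJ site, quadrupole off). Both have mass 28.014 Da and
#'   polarizability 1.710 A^3.
#' @param lj Optional replacement Lennard-Jones table: a data frame with
#'   columns `element`, `epsilon` (meV), `sigma` (Angstrom), one row per ion
#'   element.
#' @return A `drift_gas` object: list with `name`, `mass` (Da), `alpha`
#'   (polarizability, A^3), `sites` (tibble: `offset` along the gas axis in
#'   Angstrom, `lj` flag, `charge` in e) and `lj` (the parameter table).
#' @examples
#' drift_gas("N2-iso")
#' @export
drift_gas <- function(name = "N2-iso", lj = NULL) {
  name <- match.arg(name, c("N2", "N2-iso"))
  sites <- if (name == "N2") {
    tibble::tibble(
      offset = c(-0.55, 0, 0.55),
      lj = c(TRUE, FALSE, TRUE),
      charge = c(-0.4825, 0.9650, -0.4825)
    )
  } else {
    tibble::tibble(offset = 0, lj = TRUE, charge = 0)
  }
  if (is.null(lj)) lj <- .default_lj[[name]]
  lj <- tibble::as_tibble(lj)
  stopifnot(all(c("element", "epsilon", "sigma") %in% names(lj)))
  if (any(lj$epsilon <= 0) || any(lj$sigma <= 0)) {
    stop("LJ parameters must be positive", call. = FALSE)
  }
  if (abs(sum(sites$charge)) > 1e-12) {
    stop("gas point charges must sum to zero", call. = FALSE)
  }
  structure(
    list(name = name, mass = 28.014, alpha = 1.710, sites = sites, lj = lj),
    class = "drift_gas"
  )
}

#' @export
print.drift_gas <- function(x, ...) {
  cat(sprintf("<drift_gas> %s: M = %.3f Da, alpha = %.3f A^3, %d site(s)\n",
              x$name, x$mass, x$alpha, nrow(x$sites)))
  invisible(x)
}

#' Load a drift-gas model from a YAML or JSON config file
#'
#' The file must provide `name`, `mass`, `alpha`, a `sites` list (each with
#' `offset`, `lj`, `charge`) and an `lj` table keyed by element symbol with
#' `epsilon` and `sigma`. This is the override point for users with their own
#' calibrated ion-gas potentials.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `drift_gas` object.
#' @export
read_gas_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (f in c("name", "mass", "alpha", "sites", "lj")) {
    if (is.null(cfg[[f]])) stop("gas config lacks field '", f, "'", call. = FALSE)
  }
  sites <- dplyr::bind_rows(lapply(
    if (is.data.frame(cfg$sites)) split(cfg$sites, seq_len(nrow(cfg$sites)))
    else cfg$sites,
    function(s) tibble::tibble(offset = as.numeric(s$offset),
                               lj = as.logical(s$lj),
                               charge = as.numeric(s$charge))
  ))
  ljtab <- if (is.data.frame(cfg$lj)) {
    tibble::as_tibble(cfg$lj)
  } else {
    dplyr::bind_rows(purrr::imap(cfg$lj, function(v, el) {
      tibble::tibble(element = el, epsilon = as.numeric(v$epsilon),
                     sigma = as.numeric(v$sigma))
    }))
  }
  if (any(ljtab$epsilon <= 0) || any(ljtab$sigma <= 0)) {
    stop("LJ parameters must be positive", call. = FALSE)
  }
  if (abs(sum(sites$charge)) > 1e-12) {
    stop("gas point charges must sum to zero", call. = FALSE)
  }
  if (cfg$mass <= 0 || cfg$alpha <= 0) {
    stop("gas mass and polarizability must be positive", call. = FALSE)
  }
  structure(
    list(name = cfg$name, mass = as.numeric(cfg$mass),
         alpha = as.numeric(cfg$alpha), sites = sites, lj = ljtab),
    class = "drift_gas"
  )
}

# per-atom LJ parameters for an ion against a gas table; errors on unknowns
.lj_for_ion <- function(ion, gas) {
  idx <- match(ion$atoms$element, gas$lj$element)
  if (anyNA(idx)) {
    bad <- unique(ion$atoms$element[is.na(idx)])
    stop("no LJ parameters for element(s) ", paste(bad, collapse = ", "),
         " against gas ", gas$name,
         "; supply them via drift_gas(lj = ...) or a gas config file",
         call. = FALSE)
  }
  list(epsilon = gas$lj$epsilon[idx], sigma = gas$lj$sigma[idx])
}
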
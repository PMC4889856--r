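#' Read a charged-geometry XYZ file
#'
#' Reads the package's XYZ dialect: line 1 the atom count, line 2 a comment
#' that must contain `charge=<int>`, then one line per atom with
#' `element x y z partial_charge` (coordinates in Angstrom, charge in e).
#' Plain-XYZ readers can still open these files; the charge column is simply
#' a fifth field.
#'
#' @param path Path to the file.
#' @param charge_tolerance Passed to [molecular_ion()].
#' @return A [molecular_ion()].
#' @examples
#' f <- tempfile(fileext = ".xyzq")
#' write_xyzq(build_water_cluster(1), f)
#' ion <- read_xyzq(f)
#' @export
read_xyzq <- function(path, charge_tolerance = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("malformed file (fewer than 3 lines): ", path,
                              call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop("parse error at line 1: expected a positive atom count, got '",
         lines[1], "'", call. = FALSE)
  }
  comment <- lines[2]
  m <- regmatches(comment, regexec("charge=\\s*([+-]?[0-9]+)", comment))[[1]]
  if (length(m) < 2) {
    stop("parse error at line 2: comment line must contain 'charge=<int>'",
         call. = FALSE)
  }
  total_charge <- as.integer(m[2])
  if (length(lines) < 2 + n) {
    stop(sprintf("malformed file: header declares %d atoms but only %d atom lines present",
                 n, length(lines) - 2), call. = FALSE)
  }
  name <- sub("^\\s*", "", sub("charge=\\s*[+-]?[0-9]+", "", comment))
  name <- trimws(name)
  if (!nzchar(name)) name <- basename(path)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- 2 + i
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) != 5) {
      stop(sprintf("parse error at line %d: expected 5 fields (element x y z q), got %d",
                   ln, length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[2:5]))
    if (anyNA(vals)) {
      stop(sprintf("parse error at line %d: non-numeric coordinate or charge", ln),
           call. = FALSE)
    }
    rows[[i]] <- tibble::tibble(
      element = fields[1], x = vals[1], y = vals[2], z = vals[3],
      partial_charge = vals[4]
    )
  }
  molecular_ion(dplyr::bind_rows(rows), total_charge = total_charge,
                name = name, charge_tolerance = charge_tolerance)
}

#' Write a charged-geometry XYZ file
#'
#' Inverse of [read_xyzq()]; numeric content round-trips to better than
#' 1e-6 Angstrom / 1e-6 e (values are written with 8 decimals).
#'
#' @param ion A [molecular_ion()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_xyzq <- function(ion, path) {
  stopifnot(inherits(ion, "molecular_ion"))
  at <- ion$atoms
  lines <- c(
    as.character(nrow(at)),
    sprintf("%s charge=%+d", ion$name, ion$total_charge),
    sprintf("%-2s %17.10f %17.10f %17.10f %14.10f",
            at$element, at$x, at$y, at$z, at$partial_charge)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a MOBCAL-style input record
#'
#' Emits the legacy fixed-form record (atom count and charge scale header,
#' then per-atom `x y z mass q`) so that geometries prepared here can be
#' cross-checked against MOBCAL-lineage tools.
#'
#' @param ion A [molecular_ion()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mobcal <- function(ion, path) {
  stopifnot(inherits(ion, "molecular_ion"))
  at <- ion$atoms
  lines <- c(
    ion$name,
    "1",
    as.character(nrow(at)),
    "ang",
    "calc",
    "1.0000",
    sprintf("%14.6f %14.6f %14.6f %8.3f %12.6f",
            at$x, at$y, at$z, at$mass, at$partial_charge)
  )
  writeLines(lines, path)
  invisible(path)
}
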
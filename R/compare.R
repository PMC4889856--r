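#' Packaged reference mobility tables
#'
#' Two literature comparison tables shipped with the package (see the CSV
#' header blocks under `inst/extdata/` for row-by-row provenance):
#' `"water_clusters"` — reference mobilities of the hydronium water-cluster
#' series (H3O+)(H2O)n, n = 0..4, against trajectory-method values computed
#' with Mulliken, Merz-Kollman-Singh (MK) and Hirshfeld partial charges;
#' `"alkanes"` — experimental drift-tube mobilities of n-hexane through
#' n-decane (each clustered with one water) against the same three charge
#' schemes. All values in cm^2 V^-1 s^-1.
#'
#' @param which `"water_clusters"` or `"alkanes"`.
#' @return A tibble with columns `species`, `reference`, `mulliken`, `mk`,
#'   `hirshfeld`; the printed rounding of the source table (decimal places
#'   of its MUE row) is attached as attribute `"mue_digits"`, and any MUE
#'   values printed in the source as attribute `"printed_mue"`.
#' @examples
#' reference_table("alkanes")
#' @export
reference_table <- function(which = c("water_clusters", "alkanes")) {
  which <- match.arg(which)
  fname <- switch(which, water_clusters = "reference_water_clusters.csv",
                  alkanes = "reference_alkanes.csv")
  path <- system.file("extdata", fname, package = "trajmob", mustWork = TRUE)
  tab <- tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                           stringsAsFactors = FALSE))
  if (any(tab$reference <= 0)) stop("reference mobilities must be positive",
                                    call. = FALSE)
  attr(tab, "mue_digits") <- switch(which, water_clusters = 2L, alkanes = 1L)
  attr(tab, "printed_mue") <- switch(
    which,
    water_clusters = c(mulliken = 11.29, mk = 10.45, hirshfeld = 11.68),
    # the source prints 2.5 for MK in the table but 2.6 in the text;
    # recomputation from the printed columns gives 2.58 -> 2.6
    alkanes = c(mulliken = 10.9, mk = 2.6, hirshfeld = 3.0)
  )
  attr(tab, "table_id") <- which
  tab
}

#' Mean unsigned relative error between calculated and reference mobilities
#'
#' `MUE = 100 * mean(|calc - ref| / ref)` in percent. Scale-invariant:
#' rescaling both vectors by the same factor leaves it unchanged.
#'
#' @param reference Reference mobilities (> 0).
#' @param calculated Calculated mobilities, same length.
#' @return MUE in percent.
#' @examples
#' mean_unsigned_error(c(2, 2), c(1.8, 2.2))  # 10
#' @export
mean_unsigned_error <- function(reference, calculated) {
  if (length(reference) != length(calculated) || length(reference) < 1) {
    stop("reference and calculated must be equal-length, non-empty vectors",
         call. = FALSE)
  }
  if (any(reference <= 0)) {
    stop("reference mobilities must be positive", call. = FALSE)
  }
  100 * mean(abs(calculated - reference) / reference)
}

#' Compare per-scheme calculated mobilities against a reference column
#'
#' Computes the per-row unsigned relative errors and the per-scheme mean
#' unsigned error for a table with a `reference` column and one column per
#' partial-charge scheme, reproducing the summary statistics of the
#' packaged tables.
#'
#' @param table A data frame with columns `species`, `reference` and one or
#'   more scheme columns (e.g. from [reference_table()]).
#' @return A `comparison_result`: `errors` (long tibble of per-row unsigned
#'   errors, percent), `mue` (tibble of per-scheme MUE), `max_error`
#'   (largest per-row error over all schemes) and, when present on the
#'   input, the source's printed MUE values for cross-checking.
#' @examples
#' build_comparison(reference_table("water_clusters"))
#' @export
build_comparison <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("species", "reference") %in% names(table)))
  schemes <- setdiff(names(table), c("species", "reference"))
  if (length(schemes) == 0) stop("no scheme columns to compare", call. = FALSE)
  if (any(table$reference <= 0)) {
    stop("reference mobilities must be positive", call. = FALSE)
  }
  errors <- table |>
    tidyr::pivot_longer(dplyr::all_of(schemes), names_to = "scheme",
                        values_to = "calculated") |>
    dplyr::mutate(error = 100 * abs(.data$calculated - .data$reference) /
                    .data$reference)
  mue <- errors |>
    dplyr::group_by(.data$scheme) |>
    dplyr::summarise(mue = mean(.data$error), .groups = "drop")
  structure(
    list(errors = errors, mue = mue, max_error = max(errors$error),
         printed_mue = attr(table, "printed_mue"),
         mue_digits = attr(table, "mue_digits") %||% 2L,
         table_id = attr(table, "table_id")),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>",
      if (!is.null(x$table_id)) paste0("[", x$table_id, "]"), "\n")
  m <- x$mue
  for (i in seq_len(nrow(m))) {
    line <- sprintf("  %-10s MUE = %.*f%%", m$scheme[i], x$mue_digits,
                    m$mue[i])
    if (!is.null(x$printed_mue) && m$scheme[i] %in% names(x$printed_mue)) {
      line <- paste0(line, sprintf("  (source prints %.*f)", x$mue_digits,
                                   x$printed_mue[[m$scheme[i]]]))
    }
    cat(line, "\n")
  }
  cat(sprintf("  max per-row error %.2f%%\n", x$max_error))
  invisible(x)
}

#' @rdname build_comparison
#' @param x A `comparison_result`.
#' @param ... Unused.
#' @export
tidy.comparison_result <- function(x, ...) x$errors

#' @rdname build_comparison
#' @export
glance.comparison_result <- function(x, ...) {
  out <- tidyr::pivot_wider(x$mue, names_from = "scheme",
                            values_from = "mue", names_prefix = "mue_")
  out$max_error <- x$max_error
  out
}

#' Write a comparison report
#'
#' Emits the comparison both as human-readable text and as machine-readable
#' JSON (per-scheme MUE, per-row errors, max error).
#'
#' @param comparison A `comparison_result`.
#' @param path Output path stem; `<path>.txt` and `<path>.json` are written.
#' @return Invisibly, the two paths.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "comparison_result"))
  txt <- paste0(path, ".txt")
  jsn <- paste0(path, ".json")
  con <- file(txt, "w"); on.exit(close(con))
  sink(con); print(comparison); sink()
  jsonlite::write_json(
    list(mue = comparison$mue, errors = comparison$errors,
         max_error = comparison$max_error,
         printed_mue = as.list(comparison$printed_mue)),
    jsn, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(txt, jsn))
}
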
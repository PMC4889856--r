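#' Render a synthetic drift-time spectrum with calculated-mobility markers
#'
#' Emulates the figures a drift-tube comparison produces: each peak is a
#' Gaussian centered at the drift time `t_D = L^2 / (K U)` with full width at
#' half maximum `t_D / R` set by the instrument resolving power, and
#' calculated mobilities are overlaid as vertical markers at their drift
#' times.
#'
#' @param peaks A data frame with columns `K` (cm^2 V^-1 s^-1) and
#'   `intensity` (optional column `label`).
#' @param settings A [spectrum_settings()].
#' @param markers Optional data frame of calculated mobilities to mark:
#'   columns `K` and optionally `label`.
#' @return An `ims_spectrum`: `spectrum` (tibble `t` in ms vs `intensity`),
#'   `peaks` (with drift times and FWHM), `markers` (with drift times) and
#'   the settings used.
#' @examples
#' sp <- render_spectrum(data.frame(K = c(2.07, 1.92), intensity = c(1, 0.6)),
#'                       markers = data.frame(K = 1.84, label = "calc"))
#' @export
render_spectrum <- function(peaks, settings = spectrum_settings(),
                            markers = NULL) {
  stopifnot(is.data.frame(peaks), all(c("K", "intensity") %in% names(peaks)),
            all(peaks$K > 0))
  geom <- settings$geometry
  pk <- tibble::as_tibble(peaks)
  pk$t_D <- drift_from_mobility(geom, pk$K)
  pk$fwhm <- pk$t_D / settings$resolving_power
  t_range <- settings$t_range
  if (is.null(t_range)) {
    t_range <- range(pk$t_D) + c(-4, 4) * max(pk$fwhm)
    t_range[1] <- max(t_range[1], 0)
  }
  if (t_range[2] <= t_range[1]) {
    stop("drift-time axis range is empty or inverted", call. = FALSE)
  }
  t <- seq(t_range[1], t_range[2], length.out = settings$n_points)
  sig <- pk$fwhm / (2 * sqrt(2 * log(2)))
  intensity <- rowSums(vapply(seq_len(nrow(pk)), function(i) {
    pk$intensity[i] * exp(-0.5 * ((t - pk$t_D[i]) / sig[i])^2)
  }, t))
  mk <- NULL
  if (!is.null(markers)) {
    stopifnot(is.data.frame(markers), "K" %in% names(markers),
              all(markers$K > 0))
    mk <- tibble::as_tibble(markers)
    mk$t_D <- drift_from_mobility(geom, mk$K)
  }
  structure(list(spectrum = tibble::tibble(t = t, intensity = intensity),
                 peaks = pk, markers = mk, settings = settings),
            class = "ims_spectrum")
}

#' Spectrum rendering settings
#'
#' @param resolving_power Instrument resolving power `R = t_D / FWHM`
#'   (default 40, typical for compact commercial drift tubes).
#' @param geometry An [instrument_geometry()].
#' @param t_range Drift-time axis range in ms, or `NULL` to cover all peaks.
#' @param n_points Samples along the axis.
#' @return A `spectrum_settings` list.
#' @export
spectrum_settings <- function(resolving_power = 40,
                              geometry = instrument_geometry(),
                              t_range = NULL, n_points = 2000) {
  stopifnot(resolving_power > 0, inherits(geometry, "instrument_geometry"),
            n_points >= 2)
  structure(list(resolving_power = resolving_power, geometry = geometry,
                 t_range = t_range, n_points = as.integer(n_points)),
            class = "spectrum_settings")
}

#' @export
print.ims_spectrum <- function(x, ...) {
  cat(sprintf("<ims_spectrum> %d peaks, %d markers, t in [%.2f, %.2f] ms\n",
              nrow(x$peaks), if (is.null(x$markers)) 0 else nrow(x$markers),
              min(x$spectrum$t), max(x$spectrum$t)))
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a rendered drift-time spectrum
#'
#' @param object An `ims_spectrum` from [render_spectrum()].
#' @param ... Unused.
#' @return A ggplot object: intensity trace with calculated-mobility markers
#'   as vertical bars.
#' @export
autoplot.ims_spectrum <- function(object, ...) {
  p <- ggplot2::ggplot(object$spectrum,
                       ggplot2::aes(x = .data$t, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "drift time (ms)", y = "intensity (arb. u.)")
  if (!is.null(object$markers)) {
    p <- p + ggplot2::geom_vline(data = object$markers,
                                 ggplot2::aes(xintercept = .data$t_D),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}
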
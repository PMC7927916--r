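#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_vline geom_hline labs scale_fill_viridis_c facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a cross-correlation curve
#'
#' Raw and (when present) shuffle-subtracted curves against lag; negative
#' lags mean the y (V4) series leads under the [cc_hmm()] convention.
#'
#' @param object A `cross_corr`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cross_corr <- function(object, ...) {
  d <- tidy.cross_corr(object)
  p <- ggplot(d, aes(x = .data$lag_ms, y = .data$value)) +
    geom_line(colour = "grey50") +
    geom_vline(xintercept = 0, linetype = 3) +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "lag (ms)", y = object$unit)
  if (!is.null(object$corrected))
    p <- p + geom_line(aes(y = .data$corrected), colour = "black")
  p
}

#' Plot a transition-triggered average
#'
#' @param object A `tta`.
#' @param ... Unused.
#' @return A ggplot of the population trace around the alignment transition.
#' @export
autoplot.tta <- function(object, ...) {
  d <- tidy.tta(object)
  ycol <- if (!is.null(object$corrected)) "corrected" else "rate"
  ggplot(d, aes(x = .data$lag_ms, y = .data[[ycol]])) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = 3) +
    labs(x = "time from transition (ms)", y = "rate (spikes/s, mean-subtr.)")
}

#' Plot state-conditioned power spectra
#'
#' Channel-average power per state against frequency (log y).
#'
#' @param object A `spectrum_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum_set <- function(object, ...) {
  d <- tidy.spectrum_set(object) |>
    dplyr::group_by(.data$state, .data$freq) |>
    dplyr::summarise(power = mean(.data$power), .groups = "drop")
  ggplot(d, aes(x = .data$freq, y = .data$power,
                colour = factor(.data$state))) +
    geom_line() +
    ggplot2::scale_y_log10() +
    labs(x = "frequency (Hz)", y = "power", colour = "state")
}

#' Plot the cross-validation error curve
#'
#' Normalized CV error against the number of latent phases; the elbow at
#' K = 2 identifies two-phase recordings.
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$K, y = .data$norm_error)) +
    geom_line() + geom_point() +
    labs(x = "number of phases K", y = "normalized CV error")
}

#' Raster-style plot of decoded state paths
#'
#' @param object A `state_path`.
#' @param ... Unused.
#' @return A ggplot tile raster (trials x time, coloured by state).
#' @export
autoplot.state_path <- function(object, ...) {
  d <- tidy.state_path(object)
  ggplot(d, aes(x = .data$t_ms, y = factor(.data$trial),
                fill = factor(.data$state))) +
    geom_tile() +
    labs(x = "time (ms)", y = "trial", fill = "state")
}
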
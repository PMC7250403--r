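# ggplot2 visualizations. Plots are conveniences, not tested artifacts.

#' Plot an ITPC map
#'
#' Time-frequency raster of ITPC with significant (FDR-corrected) bins
#' outlined by points; frequency on a log axis, inhale onset at t = 0.
#'
#' @param object An [itpc_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.itpc_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$itpc)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$significant),
                        shape = ".", colour = "black") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Time from inhale onset (s)", y = "Frequency (Hz)",
                  fill = "ITPC",
                  subtitle = sprintf("n = %d trials", object$n_trials))
}

#' Plot a permutation z-map
#'
#' @param object A `surrogate_zmap`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.surrogate_zmap <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$significant),
                        shape = ".", colour = "black") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "Time from inhale onset (s)", y = "Frequency (Hz)",
                  fill = "z")
}

#' Plot a bootstrap difference distribution
#'
#' @param object A `bootstrap_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bootstrap_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$diff)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = object$statistic, y = "repetitions",
                  subtitle = sprintf("percentage-based p = %.3g",
                                     object$p_percent))
}

#' Plot pre-inhale PSDs per condition
#'
#' @param psd The `psd` tibble from a [run_pipeline()] bundle.
#' @return A ggplot (subject-averaged PSD per condition).
#' @export
plot_psd <- function(psd) {
  psd |>
    dplyr::group_by(.data$condition, .data$freq_hz) |>
    dplyr::summarise(psd_db = mean(.data$psd_db), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(.data$freq_hz, .data$psd_db,
                                 colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "PSD (dB)", colour = NULL)
}
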
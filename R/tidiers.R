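# broom-style tidiers: every result type flattens to a tibble.

#' Tidy an ITPC map into a long tibble
#'
#' @param x An [itpc_map()].
#' @param ... Unused.
#' @return A tibble with one row per (frequency, time) bin: `freq_hz`,
#'   `time_s`, `itpc`, `rayleigh_z`, `rayleigh_p`, `significant`.
#' @export
tidy.itpc_map <- function(x, ...) {
  tidyr::expand_grid(freq_hz = x$freq, time_s = x$time_s) |>
    dplyr::mutate(itpc = as.vector(t(x$itpc)),
                  rayleigh_z = as.vector(t(x$rayleigh_z)),
                  rayleigh_p = as.vector(t(x$rayleigh_p)),
                  significant = as.vector(t(x$sig_mask)))
}

#' Glance at an ITPC map
#'
#' @param x An [itpc_map()].
#' @param ... Unused.
#' @return A one-row tibble: `n_trials`, `max_itpc`, `n_significant`,
#'   `fdr_q`.
#' @export
glance.itpc_map <- function(x, ...) {
  tibble::tibble(n_trials = x$n_trials, max_itpc = max(x$itpc),
                 n_significant = sum(x$sig_mask), fdr_q = x$fdr_q)
}

#' Tidy a permutation z-map
#'
#' @param x A [surrogate_event_zmap()] or [label_shuffle_zmap()] result.
#' @param ... Unused.
#' @return A tibble with `freq_hz`, `time_s`, `observed_db`, `z`, `p`,
#'   `significant`.
#' @export
tidy.surrogate_zmap <- function(x, ...) {
  tidyr::expand_grid(freq_hz = x$freq, time_s = x$time_s) |>
    dplyr::mutate(observed_db = as.vector(t(x$observed)),
                  z = as.vector(t(x$z)),
                  p = as.vector(t(x$p)),
                  significant = as.vector(t(x$fdr_mask)))
}

#' Glance at a permutation z-map
#'
#' @param x A `surrogate_zmap`.
#' @param ... Unused.
#' @return A one-row tibble: `n_perm`, `max_abs_z`, `n_significant`,
#'   `fdr_q`.
#' @export
glance.surrogate_zmap <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, max_abs_z = max(abs(x$z)),
                 n_significant = sum(x$fdr_mask), fdr_q = x$fdr_q)
}

#' Tidy a bootstrap result
#'
#' @param x A [bootstrap_dmp_by_accuracy()] / [bootstrap_accuracy_by_dmp()]
#'   result.
#' @param ... Unused.
#' @return A tibble with one row per repetition: `repetition`, `diff`.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble::tibble(repetition = seq_along(x$diffs), diff = x$diffs)
}

#' Glance at a bootstrap result
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `mean_diff`, `p_percent`,
#'   `p_normal`, `p_sign`, `n_boot`, `seed`.
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, mean_diff = mean(x$diffs),
                 p_percent = x$p_percent, p_normal = x$p_normal,
                 p_sign = x$p_sign, n_boot = x$n_boot, seed = x$seed)
}
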
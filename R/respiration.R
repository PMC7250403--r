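#' Continuous nasal-airflow trace
#'
#' Light container for an airflow recording: a numeric sample vector, its
#' sampling rate, and a flag recording whether the trace has been z-scored
#' by [normalize_trace()]. Time is measured in seconds from recording start;
#' sample 1 sits at t = 0.
#'
#' @param samples Numeric vector of airflow values (arbitrary units;
#'   inhalation positive).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param normalized Has the trace already been z-scored?
#' @return An object of class `resp_trace`.
#' @export
resp_trace <- function(samples, sampling_rate_hz, normalized = FALSE) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    abort("`samples` must be a finite numeric vector.")
  }
  check_scalar(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  structure(list(samples = as.numeric(samples),
                 fs = sampling_rate_hz,
                 normalized = isTRUE(normalized)),
            class = "resp_trace")
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("<resp_trace> %d samples at %g Hz (%.1f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Z-score an airflow trace
#'
#' Subtracts the mean of the entire respiratory signal and divides by its
#' standard deviation (sample convention, n - 1), the standard
#' preprocessing before zero-crossing-based inhale detection. Idempotent up
#' to numerical precision.
#'
#' @param trace A [resp_trace()] with at least 2 samples and nonzero
#'   variance.
#' @return A normalized `resp_trace` (mean 0, SD 1, `normalized` flag set).
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "resp_trace"))
  x <- trace$samples
  if (length(x) < 2) abort("Need at least 2 samples to normalize.")
  s <- stats::sd(x)
  if (s == 0) abort("Airflow trace has zero variance; cannot normalize.")
  resp_trace((x - mean(x)) / s, trace$fs, normalized = TRUE)
}

#' Detect inhale onsets as qualified upward zero-crossings
#'
#' An inhale onset is the first nonnegative sample of an upward
#' zero-crossing that (i) is preceded by at least `min_pause_s` of strictly
#' sub-zero signal (the natural pause/exhale before a breath) and (ii) is
#' followed by an airflow excursion of at least `min_excursion` before the
#' signal returns below zero. Both criteria reject sensor jitter around
#' zero.
#'
#' @param trace A *normalized* [resp_trace()] (see [normalize_trace()]).
#' @param min_pause_s Minimum sub-zero dwell time before the crossing (s).
#' @param min_excursion Minimum post-crossing peak (normalized units).
#' @return Sorted numeric vector of onset times in seconds (possibly empty).
#' @export
detect_inhale_onsets <- function(trace, min_pause_s = 0.2,
                                 min_excursion = 0.2) {
  stopifnot(inherits(trace, "resp_trace"))
  if (!trace$normalized) {
    abort("Trace is not normalized; call normalize_trace() first.")
  }
  x <- trace$samples
  fs <- trace$fs
  n <- length(x)
  up <- which(x[-1] >= 0 & x[-n] < 0) + 1L
  if (length(up) == 0) return(numeric(0))
  np <- max(1L, round(min_pause_s * fs))
  keep <- vapply(up, function(i) {
    lo <- i - np
    if (lo < 1L) return(FALSE)
    if (any(x[lo:(i - 1L)] >= 0)) return(FALSE)
    hi <- first_sustained_negative(x, i, fs) - 1L
    max(x[i:hi]) >= min_excursion
  }, logical(1))
  (up[keep] - 1L) / fs
}

# First index >= from where the signal returns below zero and stays there
# for at least sustain_s (guards against single-sample noise blips around
# the crossing); returns length(x) + 1 if it never does.
first_sustained_negative <- function(x, from, fs, sustain_s = 0.05) {
  n <- length(x)
  ns <- max(1L, round(sustain_s * fs))
  j <- from
  while (j <= n) {
    nxt <- which(x[j:n] < 0)
    if (!length(nxt)) return(n + 1L)
    j <- j + nxt[1] - 1L
    j_end <- min(j + ns - 1L, n)
    if (all(x[j:j_end] < 0)) return(j)
    j <- j_end + 1L
  }
  n + 1L
}

#' Inhale peak and duration at one onset
#'
#' Duration is the time from the inhale onset to the first downward
#' zero-crossing; the peak is the maximum airflow value over that span.
#' The downward crossing must stay below zero for at least 50 ms, so
#' single-sample sensor blips around zero do not truncate the inhale.
#'
#' @param trace A [resp_trace()] (zero-referenced airflow).
#' @param onset_s Onset time in seconds (an upward zero-crossing).
#' @return A tibble with one row: `onset_s`, `peak`, `duration_s`.
#' @export
inhale_features <- function(trace, onset_s) {
  stopifnot(inherits(trace, "resp_trace"))
  x <- trace$samples
  fs <- trace$fs
  i0 <- round(onset_s * fs) + 1L
  if (i0 < 1L || i0 > length(x)) abort("`onset_s` lies outside the trace.")
  j <- first_sustained_negative(x, i0 + 1L, fs)
  if (j > length(x)) {
    abort("Trace ends before the inhale's next zero-crossing (truncated inhale).")
  }
  duration_s <- (j - i0) / fs
  if (duration_s <= 0) abort("`onset_s` is not an upward zero-crossing.")
  tibble::tibble(onset_s = onset_s,
                 peak = max(x[i0:(j - 1L)]),
                 duration_s = duration_s)
}

#' Label inhale onsets by anticipatory condition
#'
#' Onsets inside a trial (cue) window are anticipatory; onsets farther than
#' `guard_s` from every window are nonanticipatory; onsets inside the guard
#' band are dropped so that cue-contaminated breaths never enter the
#' nonanticipatory pool. Windows are half-open `[start, end)`.
#'
#' @param onsets Numeric vector of onset times (s).
#' @param trial_windows Data frame with columns `start` and `end`
#'   (non-overlapping, sorted).
#' @param guard_s Guard band around each window (s).
#' @return A tibble with `onset_s` and `condition`
#'   (`"anticipatory"`/`"nonanticipatory"`); dropped-onset count is attached
#'   as attribute `n_dropped` and reported via a message.
#' @export
label_events <- function(onsets, trial_windows, guard_s = 2) {
  stopifnot(is.data.frame(trial_windows),
            all(c("start", "end") %in% names(trial_windows)))
  tw <- dplyr::arrange(tibble::as_tibble(trial_windows), .data$start)
  if (nrow(tw) > 1 && any(tw$start[-1] < tw$end[-nrow(tw)])) {
    abort("`trial_windows` overlap.")
  }
  if (any(tw$end <= tw$start)) abort("`trial_windows` must have end > start.")
  lab <- vapply(onsets, function(on) {
    if (any(on >= tw$start & on < tw$end)) return("anticipatory")
    if (all(on < tw$start - guard_s | on >= tw$end + guard_s)) {
      return("nonanticipatory")
    }
    NA_character_
  }, character(1))
  dropped <- sum(is.na(lab))
  if (dropped > 0) {
    inform(sprintf("label_events: dropped %d onset(s) in the guard band.",
                   dropped))
  }
  out <- tibble::tibble(onset_s = onsets, condition = lab) |>
    dplyr::filter(!is.na(.data$condition))
  attr(out, "n_dropped") <- dropped
  out
}

#' Equalize condition counts by subsampling nonanticipatory events
#'
#' Keeps all anticipatory events and draws, without replacement, a random
#' subset of nonanticipatory events of the same size, reproducibly from
#' `seed`. Mirrors the equal-N rule used before pooling conditions, which
#' keeps ITPC sampling bias identical across conditions.
#'
#' @param events Tibble with a `condition` column.
#' @param seed Integer seed.
#' @return The subsampled events tibble (original row order preserved).
#' @export
subsample_nonanticipatory <- function(events, seed) {
  stopifnot(is.data.frame(events), "condition" %in% names(events))
  check_scalar(seed, "seed", integerish = TRUE)
  idx_a <- which(events$condition == "anticipatory")
  idx_n <- which(events$condition == "nonanticipatory")
  if (length(idx_n) < length(idx_a)) {
    abort(sprintf(
      "Need >= %d nonanticipatory events to match %d anticipatory (have %d).",
      length(idx_a), length(idx_a), length(idx_n)))
  }
  keep_n <- withr::with_seed(as.integer(seed),
                             sort(sample(idx_n, length(idx_a))))
  events[sort(c(idx_a, keep_n)), , drop = FALSE]
}
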
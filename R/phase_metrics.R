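#' Inter-trial phase coherence (phase-locking value)
#'
#' The modulus of the trial-averaged unit phasor,
#' `|mean(exp(i * phases))|`: 0 means no phase clustering across trials,
#' 1 perfect clustering. With `debias = TRUE` the small-sample bias of the
#' resultant length is removed via `sqrt(max(R^2 - 1/n, 0))` (under uniform
#' phases `E[R^2] = 1/n`, so the debiased estimate is centered at 0).
#'
#' @param phases Numeric vector of phase angles (rad), length >= 2.
#' @param debias Apply the small-sample bias correction?
#' @return A number in \[0, 1\].
#' @examples
#' itpc(c(0, pi / 2))   # 0.70711
#' @export
itpc <- function(phases, debias = FALSE) {
  if (length(phases) < 2) abort("ITPC needs at least 2 trials.")
  r <- Mod(mean(exp(1i * phases)))
  if (debias) r <- sqrt(max(r^2 - 1 / length(phases), 0))
  r
}

#' Rayleigh test of circular uniformity
#'
#' Tests phase clustering across trials: `z = n * R^2` with `R` the mean
#' resultant length, and the finite-n p-value approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`.
#'
#' @param phases Numeric vector of phase angles (rad), length >= 2.
#' @return A list with `z` and `p`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 2) abort("Rayleigh test needs at least 2 trials.")
  R <- Mod(mean(exp(1i * phases)))
  list(z = n * R^2, p = rayleigh_p(R, n))
}

# vectorized finite-n Rayleigh p approximation
rayleigh_p <- function(R, n) {
  pmin(1, exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n)))
}

#' ITPC map over a phase/amplitude tensor
#'
#' Computes ITPC, the Rayleigh z and p, and a Benjamini-Hochberg FDR
#' significance mask at every (frequency, time) bin of an epoched phase
#' tensor. FDR is applied jointly across all bins of the map.
#'
#' @param tensor A [epoch_tensor()] result with >= 2 trials.
#' @param fdr_q FDR level for the significance mask.
#' @param fdr_method `p.adjust` method: `"BH"` (default) or `"BY"`.
#' @return An object of class `itpc_map`: list with matrices `itpc`,
#'   `rayleigh_z`, `rayleigh_p`, `sig_mask` (frequency x time), plus
#'   `freq`, `time_s`, `n_trials`, `fdr_q`.
#' @export
itpc_map <- function(tensor, fdr_q = 0.05, fdr_method = c("BH", "BY")) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(inherits(tensor, "pa_tensor"))
  n <- dim(tensor$phase)[1]
  if (is.na(n) || n < 2) abort("ITPC map needs at least 2 trials.")
  d <- dim(tensor$phase)
  z <- exp(1i * tensor$phase)
  dim(z) <- c(d[1], d[2] * d[3])
  R <- matrix(Mod(colMeans(z)), d[2], d[3])
  p <- rayleigh_p(R, n)
  padj <- matrix(stats::p.adjust(p, method = fdr_method), d[2], d[3])
  structure(list(itpc = R, rayleigh_z = n * R^2, rayleigh_p = p,
                 sig_mask = padj <= fdr_q,
                 freq = tensor$freq, time_s = tensor$time_s,
                 n_trials = n, fdr_q = fdr_q),
            class = "itpc_map")
}

#' @export
print.itpc_map <- function(x, ...) {
  cat(sprintf(
    "<itpc_map> %d x %d bins (%.2g-%.3g Hz, %.2g to %.2g s), n = %d trials\n",
    nrow(x$itpc), ncol(x$itpc), min(x$freq), max(x$freq),
    min(x$time_s), max(x$time_s), x$n_trials))
  cat(sprintf("  max ITPC %.3f; %d bin(s) significant at FDR q = %g\n",
              max(x$itpc), sum(x$sig_mask), x$fdr_q))
  invisible(x)
}

#' Windowed maximum of an ITPC map
#'
#' Maximum ITPC over the inclusive sub-grid defined by `freq_window` x
#' `time_window`, with a deterministic tie-break: lowest frequency first,
#' then earliest time.
#'
#' @param map An [itpc_map()].
#' @param freq_window Length-2 inclusive frequency range (Hz).
#' @param time_window Length-2 inclusive time range (s).
#' @return A list with `value`, `freq_hz`, `time_s`.
#' @export
max_itpc <- function(map, freq_window, time_window) {
  stopifnot(inherits(map, "itpc_map"))
  fi <- which(map$freq >= freq_window[1] & map$freq <= freq_window[2])
  ti <- which(map$time_s >= time_window[1] & map$time_s <= time_window[2])
  if (!length(fi) || !length(ti)) {
    abort("Requested window does not intersect the map axes.")
  }
  sub <- map$itpc[fi, ti, drop = FALSE]
  m <- max(sub)
  hits <- which(sub == m, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  list(value = m,
       freq_hz = map$freq[fi[hits[1, 1]]],
       time_s = map$time_s[ti[hits[1, 2]]])
}

#' Rayleigh z time series at one frequency
#'
#' `z(t) = n * R(t)^2` across trials at the frequency bin nearest
#' `freq_hz` (with a warning when the match is not exact).
#'
#' @param tensor A [epoch_tensor()] result.
#' @param freq_hz Target frequency (Hz).
#' @return A tibble with `time_s` and `z`.
#' @export
rayleigh_z_timeseries <- function(tensor, freq_hz) {
  stopifnot(inherits(tensor, "pa_tensor"))
  b <- which.min(abs(tensor$freq - freq_hz))
  if (abs(tensor$freq[b] - freq_hz) > 1e-6) {
    warn(sprintf("%g Hz is off-grid; using nearest bin %.4g Hz.",
                 freq_hz, tensor$freq[b]))
  }
  n <- dim(tensor$phase)[1]
  ph <- tensor$phase[, b, , drop = TRUE]
  if (is.null(dim(ph))) ph <- matrix(ph, nrow = n)
  R <- Mod(colMeans(exp(1i * ph)))
  tibble::tibble(time_s = tensor$time_s, z = n * R^2)
}

#' Single-trial deviation from the mean phase (DMP)
#'
#' A single-trial index of phase resetting: at the epoch time `at_time`
#' (inhale onset by default), the frequency with maximal ITPC inside
#' `freq_range` is selected, the circular mean phase across trials is
#' computed there, and each trial's DMP is its absolute circular distance
#' to that mean, in \[0, pi\]. Small DMP = well-aligned trial.
#'
#' @param tensor A [epoch_tensor()] result with >= 2 trials; per-trial
#'   labels (e.g. `condition`, `correct`) are carried through.
#' @param at_time Epoch time at which to evaluate (s).
#' @param freq_range Inclusive frequency range searched for the ITPC peak.
#' @return A tibble of class `dmp_table`: one row per trial with `dmp`
#'   plus any label columns; attributes `peak_freq_hz`, `mean_phase_rad`,
#'   `resultant`.
#' @export
compute_dmp <- function(tensor, at_time = 0, freq_range = c(0.5, 2)) {
  stopifnot(inherits(tensor, "pa_tensor"))
  n <- dim(tensor$phase)[1]
  if (n < 2) abort("DMP needs at least 2 trials.")
  ti <- which.min(abs(tensor$time_s - at_time))
  fi <- which(tensor$freq >= freq_range[1] & tensor$freq <= freq_range[2])
  if (!length(fi)) abort("`freq_range` does not intersect the tensor axes.")
  ph_on <- tensor$phase[, fi, ti, drop = FALSE]
  dim(ph_on) <- c(n, length(fi))
  R <- Mod(colMeans(exp(1i * ph_on)))
  b <- which.max(R)                      # ties: lowest frequency (first hit)
  phases <- ph_on[, b]
  res <- Mod(mean(exp(1i * phases)))
  if (res < 1e-8) {
    abort("Circular mean phase undefined (resultant length ~ 0).")
  }
  mu <- Arg(sum(exp(1i * phases)))
  out <- tibble::tibble(trial = seq_len(n),
                        dmp = abs(circ_dist(phases, mu)))
  if (!is.null(tensor$labels)) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(tensor$labels))
  }
  class(out) <- c("dmp_table", class(out))
  attr(out, "peak_freq_hz") <- tensor$freq[fi[b]]
  attr(out, "mean_phase_rad") <- mu
  attr(out, "resultant") <- res
  out
}
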
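#' Preprocess a neural trace: anti-aliased downsample and z-score
#'
#' Downsamples to `target_rate_hz` with an anti-aliasing FIR (identity when
#' the rates already match), then normalizes to zero mean and unit standard
#' deviation. Single-channel operation: the common-average reference
#' degenerates to mean removal.
#'
#' @param x Numeric trace.
#' @param fs Source sampling rate (Hz), must be >= `target_rate_hz`.
#' @param target_rate_hz Target rate (Hz).
#' @return A list with `samples` (processed trace) and `fs`
#'   (= `target_rate_hz`).
#' @export
preprocess <- function(x, fs, target_rate_hz = 500) {
  check_scalar(fs, "fs", lower = 1e-9)
  check_scalar(target_rate_hz, "target_rate_hz", lower = 1e-9)
  if (target_rate_hz > fs) {
    abort(sprintf("target rate (%g Hz) exceeds source rate (%g Hz).",
                  target_rate_hz, fs))
  }
  if (target_rate_hz != fs) {
    ratio <- fs / target_rate_hz
    if (abs(ratio - round(ratio)) < 1e-9) {
      x <- signal::decimate(x, round(ratio), ftype = "fir")
    } else {
      # rational resampling for non-integer ratios
      fr <- best_rational(target_rate_hz / fs)
      x <- signal::resample(x, fr[1], fr[2])
    }
  }
  list(samples = (x - mean(x)) / stats::sd(x), fs = target_rate_hz)
}

best_rational <- function(r, max_den = 1000) {
  dens <- seq_len(max_den)
  nums <- round(r * dens)
  err <- abs(nums / dens - r)
  i <- which.min(err)
  c(nums[i], dens[i]) / gcd_int(nums[i], dens[i])
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Log-spaced band-pass filter bank
#'
#' Center frequencies are log-spaced from `f_lo` to `f_hi` inclusive, with
#' bandwidths log-spaced from `bw_lo` to `bw_hi` across the bank. Filters
#' are windowed-sinc FIRs applied forward-backward (zero phase). In
#' `fixed_bandwidth` mode the kernel spans 3 cycles of the band's low edge;
#' in `n_cycles` mode (the temporal-leakage control) it spans `cycles`
#' cycles of the center frequency. Low band edges that would fall at or
#' below 0 Hz are clipped to one third of the center frequency, with a
#' warning.
#'
#' @param f_lo,f_hi First and last center frequency (Hz).
#' @param n Number of bands (>= 2).
#' @param bw_lo,bw_hi Bandwidth at the first and last center (Hz).
#' @param mode `"fixed_bandwidth"` (default) or `"n_cycles"`.
#' @param cycles Kernel length in cycles for `n_cycles` mode.
#' @return A tibble of class `filter_bank` with columns `freq`, `bw`, `lo`,
#'   `hi`, `order_s` (kernel duration in seconds).
#' @export
make_filter_bank <- function(f_lo = 0.5, f_hi = 200, n = 50,
                             bw_lo = 1, bw_hi = 2,
                             mode = c("fixed_bandwidth", "n_cycles"),
                             cycles = 2) {
  mode <- match.arg(mode)
  stopifnot(f_lo > 0, f_hi > f_lo, n >= 2, bw_lo > 0, bw_hi >= bw_lo)
  freq <- exp(seq(log(f_lo), log(f_hi), length.out = n))
  bw <- exp(seq(log(bw_lo), log(bw_hi), length.out = n))
  lo <- freq - bw / 2
  hi <- freq + bw / 2
  clip <- lo <= 0
  if (any(clip)) {
    warn(sprintf(
      "%d band(s) had a non-positive low edge; clipped to center/3.",
      sum(clip)))
    lo[clip] <- freq[clip] / 3
  }
  order_s <- if (mode == "fixed_bandwidth") 3 / lo else cycles / freq
  out <- tibble::tibble(freq = freq, bw = bw, lo = lo, hi = hi,
                        order_s = order_s)
  class(out) <- c("filter_bank", class(out))
  attr(out, "mode") <- mode
  out
}

# Windowed-sinc band-pass kernel (Hamming, via signal::fir1); even order so
# the kernel length is odd and symmetric.
design_fir <- function(fs, lo, hi, order_s) {
  ntaps <- max(16L, 2L * round(order_s * fs / 2))
  nyq <- fs / 2
  if (hi >= nyq) abort("Band edge reaches the Nyquist frequency.")
  as.numeric(signal::fir1(ntaps, c(lo, hi) / nyq, type = "pass"))
}

# Forward-backward (zero-phase) application of an FIR kernel, computed in
# the frequency domain: multiplying by the squared magnitude response is the
# two-pass filter. O(n log n) regardless of kernel length.
apply_zero_phase <- function(x, h, analytic = FALSE) {
  n <- length(x)
  N <- next_pow2(n + 2L * length(h))
  H <- stats::fft(c(h, numeric(N - length(h))))
  G <- Mod(H)^2
  if (analytic) {
    u <- numeric(N)
    u[1] <- 1; u[N / 2 + 1] <- 1
    u[2:(N / 2)] <- 2
    G <- G * u
  }
  X <- stats::fft(c(x, numeric(N - n)))
  y <- stats::fft(X * G, inverse = TRUE) / N
  if (analytic) y[seq_len(n)] else Re(y)[seq_len(n)]
}

#' Zero-phase band-pass filter
#'
#' Filters with a windowed-sinc FIR applied forward and backward, so the net
#' phase shift is zero and the magnitude response is squared. The kernel
#' spans `order_s` seconds (default: 3 cycles of the low band edge).
#'
#' @param x Numeric signal (longer than 3 kernel lengths).
#' @param fs Sampling rate (Hz).
#' @param band Length-2 vector `c(lo, hi)` in Hz.
#' @param order_s Kernel duration in seconds; `NULL` for the default rule.
#' @return The filtered signal (same length as `x`).
#' @export
bandpass_zero_phase <- function(x, fs, band, order_s = NULL) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  order_s <- order_s %||% (3 / band[1])
  ntaps <- max(16L, 2L * round(order_s * fs / 2)) + 1L
  if (length(x) <= 3L * ntaps) {
    abort(sprintf(
      "Signal too short for the filter: need > %d samples, have %d.",
      3L * ntaps, length(x)))
  }
  h <- design_fir(fs, band[1], band[2], order_s)
  apply_zero_phase(x, h)
}

#' Instantaneous phase and amplitude via the Hilbert transform
#'
#' Computes the analytic signal of a (band-limited, zero-mean) series by the
#' FFT one-sided-spectrum construction and returns its angle and modulus.
#' The phase convention is radians in (-pi, pi\], with 0 at the local
#' maximum of a cosine.
#'
#' @param x Filtered, zero-mean numeric signal.
#' @return A list with `phase` and `amplitude` vectors.
#' @export
analytic_signal <- function(x) {
  if (all(x == 0)) abort("All-zero signal: instantaneous phase is undefined.")
  a <- fft_analytic(x)
  list(phase = Arg(a), amplitude = Mod(a))
}

#' Extract event-aligned epochs from a series
#'
#' Cuts half-open sample windows `[onset + w0, onset + w1)` around each
#' onset; the onset sample itself sits at t = 0. Epochs that would extend
#' beyond the recording are dropped and counted.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param onsets_s Event onset times (s).
#' @param window Length-2 window in seconds relative to onset.
#' @return A list: `data` (matrix, trials x time), `time_s` (epoch time
#'   axis), `kept` (indices of surviving onsets), `n_dropped`.
#' @export
epoch_series <- function(x, fs, onsets_s, window = c(-1, 3)) {
  stopifnot(length(window) == 2, window[2] > window[1])
  n <- length(x)
  i_on <- round(onsets_s * fs) + 1L
  c0 <- round(window[1] * fs)
  c1 <- round(window[2] * fs) - 1L
  ok <- (i_on + c0 >= 1L) & (i_on + c1 <= n)
  n_dropped <- sum(!ok)
  if (!any(ok)) abort("No epochs fit inside the recording.")
  if (n_dropped > 0) {
    inform(sprintf("epoch_series: dropped %d epoch(s) at recording edges.",
                   n_dropped))
  }
  offs <- c0:c1
  idx <- outer(i_on[ok], offs, `+`)
  list(data = matrix(x[idx], nrow = sum(ok)),
       time_s = offs / fs,
       kept = which(ok),
       n_dropped = n_dropped)
}

#' Moving-average smoothing of an amplitude series
#'
#' Centered moving average with a kernel of `kernel_ms` milliseconds;
#' windows shrink symmetrically at the edges. Constants pass through
#' unchanged, and the mean of interior-supported signals is preserved.
#'
#' @param x Numeric amplitude series.
#' @param fs Sampling rate (Hz).
#' @param kernel_ms Kernel duration (ms).
#' @return Smoothed series, same length.
#' @export
smooth_amplitude <- function(x, fs, kernel_ms = 10) {
  runmean_shrink(x, round(kernel_ms / 1000 * fs))
}

#' Phase/amplitude tensor: filter bank + Hilbert + epoching in one pass
#'
#' Decomposes a preprocessed trace with a [make_filter_bank()] bank (each
#' band zero-phase FIR filtered, analytic signal taken, amplitude smoothed),
#' then cuts inhale-onset-aligned epochs. The per-band filtering and
#' Hilbert transform are fused into a single frequency-domain operation,
#' numerically identical to composing [bandpass_zero_phase()] and
#' [analytic_signal()].
#'
#' @param x Numeric preprocessed trace.
#' @param fs Sampling rate (Hz).
#' @param bank A [make_filter_bank()] object.
#' @param onsets_s Event onset times (s).
#' @param window Epoch window in seconds relative to onset.
#' @param smooth_ms Amplitude smoothing kernel (ms); 0 disables.
#' @param labels Optional tibble of per-onset metadata (one row per onset,
#'   e.g. `condition`, `correct`); subset to surviving epochs.
#' @return An object of class `pa_tensor`: list with `phase` and
#'   `amplitude` arrays (trial x frequency x time), `freq` (Hz), `time_s`,
#'   `fs`, `labels`, `n_dropped`.
#' @export
epoch_tensor <- function(x, fs, bank, onsets_s, window = c(-1, 3),
                         smooth_ms = 10, labels = NULL) {
  stopifnot(inherits(bank, "filter_bank"))
  n <- length(x)
  max_taps <- max(16L, 2L * round(max(bank$order_s) * fs / 2)) + 1L
  if (n <= 3L * max_taps) {
    abort(sprintf(
      "Recording too short for the widest filter: need > %d samples.",
      3L * max_taps))
  }
  i_on <- round(onsets_s * fs) + 1L
  c0 <- round(window[1] * fs)
  c1 <- round(window[2] * fs) - 1L
  ok <- (i_on + c0 >= 1L) & (i_on + c1 <= n)
  if (!any(ok)) abort("No epochs fit inside the recording.")
  if (any(!ok)) {
    inform(sprintf("epoch_tensor: dropped %d epoch(s) at recording edges.",
                   sum(!ok)))
  }
  offs <- c0:c1
  idx <- outer(i_on[ok], offs, `+`)
  n_tr <- sum(ok)
  n_f <- nrow(bank)
  n_t <- length(offs)

  N <- next_pow2(n + 2L * max_taps)
  X <- stats::fft(c(x, numeric(N - n)))
  u <- numeric(N)
  u[1] <- 1; u[N / 2 + 1] <- 1
  u[2:(N / 2)] <- 2

  phase <- array(NA_real_, c(n_tr, n_f, n_t))
  amplitude <- array(NA_real_, c(n_tr, n_f, n_t))
  k_smooth <- round(smooth_ms / 1000 * fs)
  for (b in seq_len(n_f)) {
    h <- design_fir(fs, bank$lo[b], bank$hi[b], bank$order_s[b])
    H <- stats::fft(c(h, numeric(N - length(h))))
    a <- (stats::fft(X * (Mod(H)^2 * u), inverse = TRUE) / N)[seq_len(n)]
    ph <- Arg(a)
    am <- Mod(a)
    if (smooth_ms > 0 && k_smooth > 1) am <- runmean_shrink(am, k_smooth)
    phase[, b, ] <- ph[idx]
    amplitude[, b, ] <- am[idx]
  }
  if (!is.null(labels)) {
    stopifnot(nrow(labels) == length(onsets_s))
    labels <- labels[ok, , drop = FALSE]
  }
  structure(list(phase = phase, amplitude = amplitude,
                 freq = bank$freq, time_s = offs / fs, fs = fs,
                 labels = labels, n_dropped = sum(!ok)),
            class = "pa_tensor")
}

#' @export
print.pa_tensor <- function(x, ...) {
  cat(sprintf(
    "<pa_tensor> %d trials x %d frequencies (%.2g-%.3g Hz) x %d samples (%.2g to %.2g s)\n",
    dim(x$phase)[1], dim(x$phase)[2], min(x$freq), max(x$freq),
    dim(x$phase)[3], min(x$time_s), max(x$time_s)))
  invisible(x)
}

# subset a pa_tensor by trial index
tensor_subset <- function(tensor, rows) {
  out <- tensor
  out$phase <- tensor$phase[rows, , , drop = FALSE]
  out$amplitude <- tensor$amplitude[rows, , , drop = FALSE]
  if (!is.null(tensor$labels)) {
    out$labels <- tensor$labels[rows, , drop = FALSE]
  }
  out
}

# concatenate pa_tensors along the trial dimension (axes must match)
tensor_bind <- function(tensors) {
  stopifnot(length(tensors) >= 1)
  f <- tensors[[1]]$freq
  tt <- tensors[[1]]$time_s
  for (tn in tensors) {
    stopifnot(isTRUE(all.equal(tn$freq, f)),
              isTRUE(all.equal(tn$time_s, tt)))
  }
  ph <- do.call(abind3, lapply(tensors, `[[`, "phase"))
  am <- do.call(abind3, lapply(tensors, `[[`, "amplitude"))
  labs <- dplyr::bind_rows(lapply(tensors, `[[`, "labels"))
  structure(list(phase = ph, amplitude = am, freq = f, time_s = tt,
                 fs = tensors[[1]]$fs,
                 labels = if (nrow(labs)) labs else NULL,
                 n_dropped = sum(vapply(tensors, `[[`, 0, "n_dropped"))),
            class = "pa_tensor")
}

# bind arrays along dim 1
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n1 <- sum(vapply(arrs, function(a) dim(a)[1], 0L))
  out <- array(NA_real_, c(n1, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Trial-averaged time-frequency power map
#'
#' Squares the amplitude tensor, averages over trials, and converts to
#' decibels (10 log10). In `baseline_db` mode the per-frequency mean dB
#' over the baseline window is additionally subtracted; `raw` mode performs
#' no baseline correction (the convention for pre-event power, where
#' baseline correction would alter signal-to-noise and hence phase
#' estimates).
#'
#' @param tensor A [epoch_tensor()] result (or compatible list).
#' @param mode `"raw"` or `"baseline_db"`.
#' @param baseline_window Length-2 window (s) within the epoch.
#' @return An object of class `power_map`: list with `db` (frequency x
#'   time), `freq`, `time_s`, `mode`, `n_trials`.
#' @export
power_map <- function(tensor, mode = c("raw", "baseline_db"),
                      baseline_window = c(-1, 0)) {
  mode <- match.arg(mode)
  stopifnot(inherits(tensor, "pa_tensor"))
  if (dim(tensor$amplitude)[1] < 1) abort("Empty tensor.")
  pw <- apply(tensor$amplitude^2, c(2, 3), mean)
  db <- 10 * log10(pw)
  if (mode == "baseline_db") {
    bcols <- tensor$time_s >= baseline_window[1] &
      tensor$time_s < baseline_window[2]
    if (!any(bcols)) abort("Baseline window lies outside the epoch.")
    db <- db - rowMeans(db[, bcols, drop = FALSE])
  }
  structure(list(db = db, freq = tensor$freq, time_s = tensor$time_s,
                 mode = mode, n_trials = dim(tensor$amplitude)[1]),
            class = "power_map")
}

#' Welch power spectral density in decibels
#'
#' Averaged modified periodogram: Hann-tapered segments of `taper_s`
#' seconds with 50% overlap, zero-padded so the frequency grid has
#' `step_hz` resolution, one-sided, returned in dB.
#'
#' @param x Numeric segment (at least one taper long).
#' @param fs Sampling rate (Hz).
#' @param f_max Upper frequency of the returned grid (Hz).
#' @param step_hz Frequency grid step (Hz).
#' @param taper_s Taper length (s).
#' @return A tibble with `freq_hz` and `psd_db`.
#' @export
welch_psd <- function(x, fs, f_max = 200, step_hz = 0.05, taper_s = 4) {
  seg_len <- round(taper_s * fs)
  if (length(x) < seg_len) {
    abort(sprintf("Segment (%d samples) shorter than one %g s taper.",
                  length(x), taper_s))
  }
  if (f_max > fs / 2) abort("`f_max` exceeds the Nyquist frequency.")
  nfft <- max(round(fs / step_hz), seg_len)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)))
  hop <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, length(x) - seg_len + 1L, by = hop)
  scale <- fs * sum(w^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    S <- Mod(stats::fft(c(seg, numeric(nfft - seg_len))))^2 / scale
    half <- S[seq_len(nfft %/% 2 + 1)]
    half[2:(length(half) - 1)] <- 2 * half[2:(length(half) - 1)]
    acc <- acc + half
  }
  psd <- acc / length(starts)
  fgrid <- (seq_along(psd) - 1) * fs / nfft
  keep <- fgrid <= f_max + 1e-9
  tibble::tibble(freq_hz = fgrid[keep], psd_db = 10 * log10(psd[keep]))
}
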
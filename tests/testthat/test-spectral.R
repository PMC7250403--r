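test_that("preprocess downsamples with amplitude preservation and z-scores", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  out <- preprocess(x, fs, 500)
  expect_equal(out$fs, 500)
  expect_equal(mean(out$samples), 0, tolerance = 1e-9)
  expect_equal(sd(out$samples), 1, tolerance = 1e-9)
  # amplitude ratio against the 10 Hz content is preserved within 1%
  amp <- function(y, fsy) {
    n <- length(y)
    max(Mod(fft(y * 2 / n))[seq_len(n %/% 2)])
  }
  raw_ratio <- amp(x, fs) / sd(x)
  new_ratio <- amp(out$samples, 500) / sd(out$samples)
  expect_equal(new_ratio, raw_ratio, tolerance = 0.01)
  # identity when rates match (shape unchanged up to normalization)
  y <- sin(2 * pi * 7 * seq(0, 5, by = 1 / 500)) + 2
  id <- preprocess(y, 500, 500)
  expect_length(id$samples, length(y))
  expect_equal(cor(id$samples, y), 1, tolerance = 1e-12)
  expect_error(preprocess(x, 500, 1000), "exceeds")
})

test_that("make_filter_bank reproduces the log-spaced design", {
  suppressWarnings(bank <- make_filter_bank())
  expect_identical(nrow(bank), 50L)
  expect_equal(bank$freq[1], 0.5)
  expect_equal(bank$freq[50], 200)
  expect_equal(bank$bw[1], 1)
  expect_equal(bank$bw[50], 2)
  expect_true(all(diff(bank$freq) > 0))
  expect_true(all(diff(bank$bw) > 0))
  expect_true(all(bank$lo > 0))
  expect_warning(make_filter_bank(), "clipped")
  # n_cycles mode: kernel spans cycles / center frequency
  b2 <- suppressWarnings(make_filter_bank(mode = "n_cycles", cycles = 2))
  expect_equal(b2$order_s, 2 / b2$freq)
})

test_that("zero-phase band-pass has no lag, strong stopband, time symmetry", {
  fs <- 250
  t <- seq(0, 120, by = 1 / fs)
  x1 <- sin(2 * pi * 1 * t)
  x50 <- sin(2 * pi * 50 * t)
  y <- bandpass_zero_phase(x1 + x50, fs, c(0.5, 1.5))
  # no lag: cross-correlation with the in-band component peaks at 0
  lags <- -20:20
  cc <- vapply(lags, function(L) {
    idx <- 3000:27000
    cor(y[idx], x1[idx + L])
  }, numeric(1))
  expect_identical(lags[which.max(cc)], 0L)
  # out-of-band attenuation > 20 dB (FFT oracle on the output)
  pow_at <- function(sig, f) {
    n <- length(sig)
    Mod(fft(sig))[round(f * n / fs) + 1]^2
  }
  expect_gt(10 * log10(pow_at(x1 + x50, 50) / pow_at(y, 50)), 20)
  # in-band attenuation < 1 dB
  expect_lt(abs(10 * log10(pow_at(x1, 1) / pow_at(y, 1))), 1)
  # time-reversal symmetry of the two-pass filter
  yr <- bandpass_zero_phase(rev(x1 + x50), fs, c(0.5, 1.5))
  expect_equal(rev(yr), y, tolerance = 1e-9)
  expect_error(bandpass_zero_phase(rnorm(100), fs, c(0.5, 1.5)),
               "too short")
})

test_that("analytic_signal extracts phase and amplitude of a tone", {
  fs <- 200
  t <- seq(0, 30, by = 1 / fs)
  x <- cos(2 * pi * 1 * t)
  a <- analytic_signal(x)
  interior <- seq(5 * fs, 25 * fs)
  # amplitude 1 within 2% away from the edges
  expect_lt(max(abs(a$amplitude[interior] - 1)), 0.02)
  # phase 0 at signal peaks
  peaks <- which(abs(t %% 1) < 1e-9 & t > 5 & t < 25)
  expect_lt(max(abs(a$phase[peaks])), 0.05)
  # linear amplitude scaling
  a2 <- analytic_signal(0.5 * x)
  expect_lt(max(abs(a2$amplitude[interior] - 0.5)), 0.01)
  # monotone unwrapped phase for a pure tone
  dph <- diff(a$phase[interior])
  dph[dph < -pi] <- dph[dph < -pi] + 2 * pi
  expect_true(all(dph > 0))
  expect_error(analytic_signal(numeric(100)), "undefined")
})

test_that("epoch_series cuts half-open sample windows and drops edges", {
  fs <- 500
  x <- rnorm(10 * fs)
  ep <- suppressMessages(epoch_series(x, fs, c(2, 5, 0.5), c(-1, 3)))
  expect_identical(ncol(ep$data), 2000L)    # (3 - (-1)) * 500, half-open
  expect_identical(ep$kept, c(1L, 2L))      # onset at 0.5 s is dropped
  expect_identical(ep$n_dropped, 1L)
  # epoching a constant series yields identical epochs
  epc <- epoch_series(rep(3, 10 * fs), fs, c(2, 5), c(-1, 1))
  expect_identical(epc$data[1, ], epc$data[2, ])
  expect_error(epoch_series(x, fs, 100, c(-1, 3)), "No epochs")
})

test_that("smooth_amplitude is a centered shrinking-edge moving average", {
  fs <- 500
  expect_identical(smooth_amplitude(rep(2, 100), fs, 10), rep(2, 100))
  # unit impulse with a 10 ms (5-sample) kernel spreads to 0.2 x 5
  imp <- numeric(101); imp[51] <- 1
  sm <- smooth_amplitude(imp, fs, 10)
  expect_equal(sm[49:53], rep(0.2, 5))
  expect_equal(sum(sm != 0), 5L)
  # mean preserved for interior-supported signals (margin of a full
  # kernel of zeros, so every nonzero value is covered by full windows)
  x <- c(rep(0, 5), abs(withr::with_seed(4, rnorm(90))), rep(0, 5))
  expect_equal(mean(smooth_amplitude(x, fs, 10)), mean(x),
               tolerance = 1e-12)
})

test_that("power_map converts amplitude to trial-averaged dB power", {
  ph <- array(runif(2 * 3 * 100, -pi, pi), c(2, 3, 100))
  tens <- fake_tensor(ph, time_s = seq(-1, 0.98, by = 0.02),
                      amplitude = array(2, c(2, 3, 100)))
  pm <- power_map(tens, "raw")
  expect_true(all(abs(pm$db - 10 * log10(4)) < 1e-12))
  # doubling amplitudes shifts the raw map by +6.0206 dB
  tens2 <- tens; tens2$amplitude <- tens$amplitude * 2
  pm2 <- power_map(tens2, "raw")
  expect_equal(pm2$db - pm$db, matrix(20 * log10(2), 3, 100),
               tolerance = 1e-9)
  # baseline mode zeroes the baseline-window mean per frequency
  tens3 <- tens
  tens3$amplitude <- array(rexp(2 * 3 * 100) + 0.1, c(2, 3, 100))
  pm3 <- power_map(tens3, "baseline_db", baseline_window = c(-1, -0.5))
  bcols <- pm3$time_s >= -1 & pm3$time_s < -0.5
  expect_equal(rowMeans(pm3$db[, bcols]), rep(0, 3), tolerance = 1e-9)
  expect_error(power_map(tens, "baseline_db",
                         baseline_window = c(5, 6)), "Baseline")
})

test_that("welch_psd is flat for white noise and localizes tones", {
  withr::with_seed(1, {
    w <- welch_psd(rnorm(1e5), 500, f_max = 200, step_hz = 0.05,
                   taper_s = 4)
    expect_lt(sd(w$psd_db[w$freq_hz > 1]), 2)
  })
  t <- seq(0, 100, by = 1 / 500)
  w2 <- welch_psd(sin(2 * pi * 10 * t), 500, f_max = 200, step_hz = 0.05,
                  taper_s = 4)
  expect_lt(abs(w2$freq_hz[which.max(w2$psd_db)] - 10), 0.05 + 1e-9)
  # Parseval scaling: doubling the signal lifts the PSD by 6.0206 dB
  x <- withr::with_seed(2, rnorm(20000))
  wa <- welch_psd(x, 500, taper_s = 4)
  wb <- welch_psd(2 * x, 500, taper_s = 4)
  expect_equal(wb$psd_db - wa$psd_db,
               rep(20 * log10(2), nrow(wa)), tolerance = 1e-9)
  expect_error(welch_psd(rnorm(100), 500, taper_s = 4), "shorter")
})

test_that("filter-to-phase fidelity holds at bank center frequencies", {
  fs <- 250
  bank <- suppressWarnings(make_filter_bank(0.5, 30, 8))
  t <- seq(0, 150, by = 1 / fs)
  for (b in c(1, 4, 8)) {
    f0 <- bank$freq[b]
    x <- cos(2 * pi * f0 * t)
    tens <- suppressMessages(
      epoch_tensor(x, fs, bank[b, ], onsets_s = c(60, 80),
                   window = c(-1, 1), smooth_ms = 0))
    # phase at epoch t = 0 (onset at integer seconds only for f0 integer);
    # compare against the analytic phase of the tone instead
    ti <- which.min(abs(tens$time_s))
    for (tr in 1:2) {
      on <- c(60, 80)[tr]
      true_phase <- ((2 * pi * f0 * on + pi) %% (2 * pi)) - pi
      err <- abs(Arg(exp(1i * (tens$phase[tr, 1, ti] - true_phase))))
      expect_lt(err, 0.1)
    }
  }
})

test_that("fused tensor path equals composed filter + Hilbert operations", {
  fs <- 200
  x <- withr::with_seed(3, rnorm(120 * fs))
  bank <- make_filter_bank(2, 8, 3)
  tens <- suppressMessages(
    epoch_tensor(x, fs, bank, onsets_s = c(30, 60, 90),
                 window = c(-1, 1), smooth_ms = 0))
  for (b in 1:3) {
    filt <- bandpass_zero_phase(x, fs, c(bank$lo[b], bank$hi[b]),
                                order_s = bank$order_s[b])
    asig <- analytic_signal(filt)
    ep <- suppressMessages(
      epoch_series(asig$phase, fs, c(30, 60, 90), c(-1, 1)))
    # phases agree up to the two paths' different FFT padding
    d <- atan2(sin(tens$phase[, b, ] - ep$data),
               cos(tens$phase[, b, ] - ep$data))
    expect_lt(max(abs(d)), 0.005)
  }
})

test_that("pre-onset leakage of a post-onset theta response stays at the null level", {
  fs <- 250
  bank2 <- suppressWarnings(
    make_filter_bank(0.5, 2, 4, mode = "n_cycles", cycles = 2))
  onsets <- seq(20, 380, length.out = 40)
  pre_itpc <- function(seed, evoked) {
    x <- withr::with_seed(seed, rnorm(400 * fs))
    if (evoked) {
      tt <- seq(0, 1, by = 1 / fs)
      burst <- 3 * sin(2 * pi * 6 * tt) * 0.5 * (1 - cos(2 * pi * tt))
      for (o in onsets) {
        i0 <- round(o * fs) + 1L
        x[i0:(i0 + length(burst) - 1L)] <-
          x[i0:(i0 + length(burst) - 1L)] + burst
      }
    }
    tens <- suppressMessages(
      epoch_tensor(x, fs, bank2, onsets, window = c(-1, 1), smooth_ms = 0))
    m <- itpc_map(tens)
    mean(m$itpc[, m$time_s >= -1 & m$time_s <= -0.6])
  }
  null_vals <- vapply(1:12, function(s) pre_itpc(s, FALSE), numeric(1))
  ev_val <- pre_itpc(100, TRUE)
  expect_lte(ev_val, quantile(null_vals, 0.95))
})

test_that("fixed-bandwidth and 2-cycle banks agree on the reset cluster location", {
  ds <- generate_dataset(quick_cfg(seed = 9, n_anticipatory = 50,
                                   sampling_rate_hz = 250))
  x <- (ds$neural - mean(ds$neural)) / sd(ds$neural)
  onsets <- ds$truth$breaths$onset_s[ds$truth$breaths$is_trial]
  centroid <- function(bank) {
    tens <- suppressMessages(
      epoch_tensor(x, 250, bank, onsets, window = c(-1, 1)))
    m <- itpc_map(tens)
    fi <- which(m$freq >= 0.5 & m$freq <= 2)
    ti <- which(m$time_s >= -1 & m$time_s <= 0)
    hit <- which(m$sig_mask[fi, ti], arr.ind = TRUE)
    expect_gt(nrow(hit), 0)
    c(fbin = mean(hit[, 1]), t = mean(m$time_s[ti][hit[, 2]]))
  }
  l1 <- centroid(suppressWarnings(make_filter_bank(0.5, 8, 10)))
  l2 <- centroid(suppressWarnings(
    make_filter_bank(0.5, 8, 10, mode = "n_cycles", cycles = 2)))
  expect_lte(abs(l1["fbin"] - l2["fbin"]), 1)
  expect_lte(abs(l1["t"] - l2["t"]), 0.1)
})
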
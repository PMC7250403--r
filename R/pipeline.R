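#' Analysis configuration for the end-to-end pipeline
#'
#' Collects every parameter [run_pipeline()] consumes, with explicit seeds
#' for every stage that uses randomness. Configurations round-trip
#' losslessly through YAML ([write_analysis_config()]).
#'
#' @param mode `"synthetic"` (simulate a cohort) or `"files"` (read
#'   recordings written by [write_dataset()]).
#' @param n_subjects Number of simulated subjects (synthetic mode). The
#'   subject-level statistics (paired tests, median split) need at least
#'   3 subjects; the ANOVA and correlations are skipped below 3 and 4.
#' @param synth Named list of [synth_config()] overrides applied to every
#'   simulated subject (each subject gets its own derived seed).
#' @param paths Character vector of dataset directories (files mode).
#' @param target_rate_hz Analysis sampling rate after [preprocess()].
#' @param bank Named list of [make_filter_bank()] arguments.
#' @param epoch_window Epoch window around inhale onset (s).
#' @param pre_window,post_window Pre-inhale and post-inhale analysis
#'   windows (s).
#' @param baseline_window Baseline window for dB-corrected post-inhale
#'   power (s).
#' @param itpc_freq_range Frequency range for windowed ITPC maxima and the
#'   DMP peak-frequency search (Hz).
#' @param power_freq_range Frequency range for windowed power maxima (Hz).
#' @param theta_freq_range Frequency range of the post-inhale theta
#'   effect (Hz).
#' @param guard_s Guard band for event labeling (s).
#' @param min_pause_s,min_excursion Inhale-onset detection parameters.
#' @param smooth_ms Amplitude smoothing kernel (ms).
#' @param fdr_q FDR level for all maps.
#' @param n_perm Permutations for z-maps (>= 1).
#' @param n_boot Bootstrap repetitions (>= 1).
#' @param dmp_quantile Extreme-group fraction for the accuracy-by-DMP
#'   bootstrap.
#' @param psd_step_hz,psd_taper_s Welch PSD grid step and taper length.
#' @param compute_surrogate Also compute the surrogate-event z-map for the
#'   pooled anticipatory condition (slower)?
#' @param scramble_conditions Negative control: randomly reassign condition
#'   labels (preserving counts) before analysis.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("synthetic", "files"),
                            n_subjects = 13,
                            synth = list(),
                            paths = character(),
                            target_rate_hz = 250,
                            bank = list(f_lo = 0.5, f_hi = 30, n = 20,
                                        bw_lo = 1, bw_hi = 2),
                            epoch_window = c(-1, 3),
                            pre_window = c(-1, 0),
                            post_window = c(0, 1),
                            baseline_window = c(-1, 0),
                            itpc_freq_range = c(0.5, 2),
                            power_freq_range = c(0.5, 12),
                            theta_freq_range = c(4, 8),
                            guard_s = 2,
                            min_pause_s = 0.2,
                            min_excursion = 0.2,
                            smooth_ms = 10,
                            fdr_q = 0.05,
                            n_perm = 200,
                            n_boot = 1000,
                            dmp_quantile = 0.2,
                            psd_step_hz = 0.05,
                            psd_taper_s = 1,
                            compute_surrogate = FALSE,
                            scramble_conditions = FALSE,
                            seed) {
  mode <- match.arg(mode)
  if (missing(seed)) abort("`seed` is mandatory in analysis_config().")
  check_scalar(seed, "seed", integerish = TRUE)
  check_scalar(n_perm, "n_perm", lower = 1, integerish = TRUE)
  check_scalar(n_boot, "n_boot", lower = 1, integerish = TRUE)
  check_scalar(target_rate_hz, "target_rate_hz", lower = 1e-9)
  check_scalar(fdr_q, "fdr_q", lower = 1e-9, upper = 1)
  check_scalar(dmp_quantile, "dmp_quantile", lower = 1e-9, upper = 0.5)
  if (mode == "synthetic") {
    check_scalar(n_subjects, "n_subjects", lower = 1, integerish = TRUE)
  } else if (!length(paths)) {
    abort("files mode requires `paths`.")
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  mode %s; %s; analysis rate %g Hz; seed %d\n", x$mode,
              if (x$mode == "synthetic")
                sprintf("%d simulated subjects", x$n_subjects)
              else sprintf("%d recordings", length(x$paths)),
              x$target_rate_hz, x$seed))
  cat(sprintf("  bank: %d bands %g-%g Hz; n_perm %d; n_boot %d; FDR q %g\n",
              x$bank$n, x$bank$f_lo, x$bank$f_hi, x$n_perm, x$n_boot,
              x$fdr_q))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Generates `n_subjects` independent datasets sharing the same generator
#' parameters; each subject's [synth_config()] seed is derived
#' deterministically from `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param seed Master seed.
#' @param ... Overrides passed to [synth_config()].
#' @return A list of [generate_dataset()] results.
#' @export
simulate_cohort <- function(n_subjects, seed, ...) {
  check_scalar(n_subjects, "n_subjects", lower = 1, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1,
                                           n_subjects))
  lapply(seq_len(n_subjects), function(s) {
    generate_dataset(synth_config(..., seed = sub_seeds[s]))
  })
}

# Per-subject stage: respiration -> events -> tensor -> maps and scalars.
analyze_subject <- function(ds, subject_id, cfg, bank, sub_seed) {
  resp <- normalize_trace(ds$respiration)
  onsets <- detect_inhale_onsets(resp, cfg$min_pause_s, cfg$min_excursion)
  events <- suppressMessages(
    label_events(onsets, ds$trial_windows, guard_s = cfg$guard_s))
  feats <- dplyr::bind_rows(lapply(events$onset_s, function(on) {
    inhale_features(resp, on)
  }))
  events <- dplyr::left_join(events, feats, by = "onset_s")
  # attach behavioral accuracy by matching truth onsets (within one sample)
  truth <- ds$truth$breaths
  nearest <- vapply(events$onset_s, function(on) {
    which.min(abs(truth$onset_s - on))
  }, integer(1))
  events$correct <- truth$correct[nearest]
  events <- subsample_nonanticipatory(events, seed = sub_seed)
  if (isTRUE(cfg$scramble_conditions)) {
    events$condition <- withr::with_seed(sub_seed + 1L,
                                         sample(events$condition))
    events$correct[events$condition != "anticipatory"] <- NA
    events$correct[events$condition == "anticipatory" &
                     is.na(events$correct)] <- TRUE
  }
  pp <- preprocess(ds$neural, ds$fs, cfg$target_rate_hz)
  labels <- tibble::tibble(subject = subject_id,
                           condition = events$condition,
                           correct = events$correct,
                           inhale_peak = events$peak,
                           inhale_duration_s = events$duration_s)
  tensor <- suppressMessages(
    epoch_tensor(pp$samples, pp$fs, bank, events$onset_s,
                 window = cfg$epoch_window, smooth_ms = cfg$smooth_ms,
                 labels = labels))
  idx_a <- which(tensor$labels$condition == "anticipatory")
  idx_n <- which(tensor$labels$condition == "nonanticipatory")
  tens_a <- tensor_subset(tensor, idx_a)
  tens_n <- tensor_subset(tensor, idx_n)

  map_a <- itpc_map(tens_a, fdr_q = cfg$fdr_q)
  map_n <- itpc_map(tens_n, fdr_q = cfg$fdr_q)

  max_tbl <- tidyr::expand_grid(
    condition = c("anticipatory", "nonanticipatory"),
    time_window = c("early", "late")) |>
    dplyr::rowwise() |>
    dplyr::mutate(window_start = ifelse(.data$time_window == "early", -1, -0.5),
                  window_end = ifelse(.data$time_window == "early", -0.5, 0),
                  itpc_max = max_itpc(
                    if (.data$condition == "anticipatory") map_a else map_n,
                    cfg$itpc_freq_range,
                    c(.data$window_start, .data$window_end))$value) |>
    dplyr::ungroup() |>
    dplyr::mutate(subject = subject_id, .before = 1)

  pre_cols <- tensor$time_s >= cfg$pre_window[1] &
    tensor$time_s < cfg$pre_window[2]
  post_cols <- tensor$time_s >= cfg$post_window[1] &
    tensor$time_s < cfg$post_window[2]
  pw_rng <- tensor$freq >= cfg$power_freq_range[1] &
    tensor$freq <= cfg$power_freq_range[2]
  th_rng <- tensor$freq >= cfg$theta_freq_range[1] &
    tensor$freq <= cfg$theta_freq_range[2]

  pm_a_raw <- power_map(tens_a, "raw")
  pm_n_raw <- power_map(tens_n, "raw")
  pm_a_db <- power_map(tens_a, "baseline_db",
                       baseline_window = cfg$baseline_window)
  pm_n_db <- power_map(tens_n, "baseline_db",
                       baseline_window = cfg$baseline_window)
  scalars <- tibble::tibble(
    subject = subject_id,
    itpc_pre_ant = max_itpc(map_a, cfg$itpc_freq_range, c(-0.5, 0))$value,
    itpc_pre_non = max_itpc(map_n, cfg$itpc_freq_range, c(-0.5, 0))$value,
    pre_power_ant = max(pm_a_raw$db[pw_rng, pre_cols]),
    pre_power_non = max(pm_n_raw$db[pw_rng, pre_cols]),
    post_theta_ant = max(pm_a_db$db[th_rng, post_cols]),
    post_theta_non = max(pm_n_db$db[th_rng, post_cols]),
    inhale_peak_ant = mean(labels$inhale_peak[idx_a]),
    inhale_peak_non = mean(labels$inhale_peak[idx_n]),
    inhale_dur_ant = mean(labels$inhale_duration_s[idx_a]),
    inhale_dur_non = mean(labels$inhale_duration_s[idx_n]))

  dmp_tbl <- compute_dmp(tens_a, at_time = 0,
                         freq_range = cfg$itpc_freq_range)

  # pre-inhale PSD per condition: per-epoch Welch averaged in linear power
  psd_of <- function(x, fs, onsets) {
    ep <- suppressMessages(epoch_series(x, fs, onsets, cfg$pre_window))
    grids <- apply(ep$data, 1, function(seg) {
      welch_psd(seg, fs, f_max = min(cfg$bank$f_hi, fs / 2 * 0.98),
                step_hz = cfg$psd_step_hz,
                taper_s = min(cfg$psd_taper_s, length(seg) / fs))
    })
    freq <- grids[[1]]$freq_hz
    lin <- rowMeans(vapply(grids, function(g) 10^(g$psd_db / 10),
                           numeric(length(freq))))
    tibble::tibble(freq_hz = freq, psd_db = 10 * log10(lin))
  }
  psd <- dplyr::bind_rows(
    psd_of(pp$samples, pp$fs, events$onset_s[idx_a]) |>
      dplyr::mutate(condition = "anticipatory"),
    psd_of(pp$samples, pp$fs, events$onset_s[idx_n]) |>
      dplyr::mutate(condition = "nonanticipatory")) |>
    dplyr::mutate(subject = subject_id)

  list(tensor = tensor, idx_a = idx_a, idx_n = idx_n,
       map_a = map_a, map_n = map_n, max_tbl = max_tbl,
       scalars = scalars, dmp = dmp_tbl, psd = psd, events = events,
       pp = pp)
}

#' Run the full phase-reset analysis pipeline
#'
#' Executes respiration processing, spectral decomposition, ITPC and DMP
#' analysis and all resampling statistics over a simulated cohort
#' (synthetic mode) or saved recordings (files mode), in that order, and
#' collects every table and map into a results bundle. All randomness is
#' seeded from `config$seed`, so reruns with an identical configuration are
#' bit-identical.
#'
#' @param config An [analysis_config()].
#' @return An object of class `results_bundle`; see Details.
#' @details The bundle contains: `itpc_combined` (per-condition pooled
#'   [itpc_map()]s), `itpc_subject` (per-subject maps), `max_itpc_table`
#'   (per subject x condition x half-window maxima), `anova` (2 x 2
#'   repeated-measures ANOVA on those maxima), `paired` (paired t tests for
#'   ITPC, pre-inhale power, post-inhale theta power, inhale peak and
#'   duration), `pre_power_zmap` / `post_power_zmap` (label-shuffle
#'   permutation maps), optional `surrogate_zmap`, `psd` (per-subject
#'   pre-inhale Welch PSD), `dmp` (pooled DMP table),
#'   `boot_dmp_by_accuracy` / `boot_accuracy_by_dmp` (bootstraps),
#'   `median_split`, `correlations`, `subject_scalars`, `respiration`
#'   (per-event features) and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cfg <- config
  stage_seeds <- withr::with_seed(cfg$seed,
                                  sample.int(.Machine$integer.max - 1, 6))
  bank <- do.call(make_filter_bank, cfg$bank)

  datasets <- if (cfg$mode == "synthetic") {
    do.call(simulate_cohort,
            c(list(n_subjects = cfg$n_subjects, seed = stage_seeds[1]),
              cfg$synth))
  } else {
    lapply(cfg$paths, read_dataset)
  }
  n_sub <- length(datasets)
  sub_seeds <- withr::with_seed(stage_seeds[2],
                                sample.int(.Machine$integer.max - 1, n_sub))

  subjects <- lapply(seq_len(n_sub), function(s) {
    analyze_subject(datasets[[s]], s, cfg, bank, sub_seeds[s])
  })

  # ---- combined (pooled) analyses -----------------------------------------
  tens_a <- tensor_bind(lapply(subjects, function(su)
    tensor_subset(su$tensor, su$idx_a)))
  tens_n <- tensor_bind(lapply(subjects, function(su)
    tensor_subset(su$tensor, su$idx_n)))
  itpc_combined <- list(anticipatory = itpc_map(tens_a, fdr_q = cfg$fdr_q),
                        nonanticipatory = itpc_map(tens_n, fdr_q = cfg$fdr_q))

  pre_cols <- tens_a$time_s >= cfg$pre_window[1] &
    tens_a$time_s < cfg$pre_window[2]
  pow_a <- tens_a$amplitude^2
  pow_n <- tens_n$amplitude^2
  pre_power_zmap <- label_shuffle_zmap(
    pow_a[, , pre_cols, drop = FALSE], pow_n[, , pre_cols, drop = FALSE],
    freq = tens_a$freq, time_s = tens_a$time_s[pre_cols],
    n_perm = cfg$n_perm, seed = stage_seeds[3], fdr_q = cfg$fdr_q)
  post_power_zmap <- label_shuffle_zmap(
    pow_a, pow_n, freq = tens_a$freq, time_s = tens_a$time_s,
    n_perm = cfg$n_perm, seed = stage_seeds[4], fdr_q = cfg$fdr_q)

  surrogate <- NULL
  if (isTRUE(cfg$compute_surrogate)) {
    su1 <- subjects[[1]]
    amp <- bank_power(su1$pp$samples, su1$pp$fs, bank, cfg$smooth_ms)
    surrogate <- surrogate_event_zmap(
      amp, su1$pp$fs,
      su1$events$onset_s[su1$events$condition == "anticipatory"],
      window = cfg$epoch_window, freq = bank$freq,
      n_perm = cfg$n_perm, seed = stage_seeds[5], fdr_q = cfg$fdr_q)
  }

  dmp_all <- dplyr::bind_rows(lapply(subjects, function(su) {
    tibble::as_tibble(su$dmp) |>
      dplyr::mutate(peak_freq_hz = attr(su$dmp, "peak_freq_hz"))
  }))
  boot_seeds <- withr::with_seed(stage_seeds[6],
                                 sample.int(.Machine$integer.max - 1, 2))
  boot1 <- bootstrap_dmp_by_accuracy(dmp_all, n_boot = cfg$n_boot,
                                     seed = boot_seeds[1])
  boot2 <- bootstrap_accuracy_by_dmp(dmp_all, quantile = cfg$dmp_quantile,
                                     n_boot = cfg$n_boot,
                                     seed = boot_seeds[2])

  scalars <- dplyr::bind_rows(lapply(subjects, `[[`, "scalars"))
  max_tbl <- dplyr::bind_rows(lapply(subjects, `[[`, "max_tbl"))
  anova <- if (n_sub < 3) NULL else rm_anova_2x2(max_tbl |>
                          dplyr::transmute(subject = .data$subject,
                                           factor_a = .data$condition,
                                           factor_b = .data$time_window,
                                           value = .data$itpc_max))
  paired <- dplyr::bind_rows(
    paired_tests(scalars$itpc_pre_ant, scalars$itpc_pre_non) |>
      dplyr::mutate(measure = "itpc_pre", .before = 1),
    paired_tests(scalars$pre_power_ant, scalars$pre_power_non) |>
      dplyr::mutate(measure = "pre_power", .before = 1),
    paired_tests(scalars$post_theta_ant, scalars$post_theta_non) |>
      dplyr::mutate(measure = "post_theta_power", .before = 1),
    paired_tests(scalars$inhale_peak_ant, scalars$inhale_peak_non) |>
      dplyr::mutate(measure = "inhale_peak", .before = 1),
    paired_tests(scalars$inhale_dur_ant, scalars$inhale_dur_non) |>
      dplyr::mutate(measure = "inhale_duration", .before = 1))

  correlations <- if (n_sub < 4) tibble::tibble() else dplyr::bind_rows(
    correlate_pairs(scalars$itpc_pre_ant - scalars$itpc_pre_non,
                    scalars$post_theta_ant - scalars$post_theta_non) |>
      dplyr::mutate(pair = "itpc_diff~post_theta_diff", .before = 1),
    correlate_pairs(scalars$itpc_pre_ant - scalars$itpc_pre_non,
                    scalars$pre_power_ant - scalars$pre_power_non) |>
      dplyr::mutate(pair = "itpc_diff~pre_power_diff", .before = 1),
    correlate_pairs(scalars$itpc_pre_ant - scalars$itpc_pre_non,
                    scalars$inhale_peak_ant - scalars$inhale_peak_non) |>
      dplyr::mutate(pair = "itpc_diff~inhale_peak_diff", .before = 1),
    correlate_pairs(scalars$itpc_pre_ant - scalars$itpc_pre_non,
                    scalars$inhale_dur_ant - scalars$inhale_dur_non) |>
      dplyr::mutate(pair = "itpc_diff~inhale_duration_diff", .before = 1))

  med_split <- median_split_compare(dmp_all)

  respiration <- dplyr::bind_rows(lapply(seq_along(subjects), function(s) {
    subjects[[s]]$events |>
      dplyr::mutate(subject = s, .before = 1)
  }))

  bundle <- structure(list(
    itpc_combined = itpc_combined,
    itpc_subject = lapply(subjects, function(su)
      list(anticipatory = su$map_a, nonanticipatory = su$map_n)),
    max_itpc_table = max_tbl,
    anova = anova,
    paired = paired,
    pre_power_zmap = pre_power_zmap,
    post_power_zmap = post_power_zmap,
    surrogate_zmap = surrogate,
    psd = dplyr::bind_rows(lapply(subjects, `[[`, "psd")),
    dmp = dmp_all,
    boot_dmp_by_accuracy = boot1,
    boot_accuracy_by_dmp = boot2,
    median_split = med_split,
    correlations = correlations,
    subject_scalars = scalars,
    respiration = respiration,
    provenance = list(
      package_version = as.character(utils::packageVersion("respitpc")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = cfg$seed, stage_seeds = stage_seeds,
      config = unclass(cfg))
  ), class = "results_bundle")
  bundle
}

# full-recording smoothed power matrix (frequency x sample) for one trace
bank_power <- function(x, fs, bank, smooth_ms = 10) {
  n <- length(x)
  max_taps <- max(16L, 2L * round(max(bank$order_s) * fs / 2)) + 1L
  N <- next_pow2(n + 2L * max_taps)
  X <- stats::fft(c(x, numeric(N - n)))
  u <- numeric(N)
  u[1] <- 1; u[N / 2 + 1] <- 1
  u[2:(N / 2)] <- 2
  k_smooth <- round(smooth_ms / 1000 * fs)
  out <- matrix(NA_real_, nrow(bank), n)
  for (b in seq_len(nrow(bank))) {
    h <- design_fir(fs, bank$lo[b], bank$hi[b], bank$order_s[b])
    H <- stats::fft(c(h, numeric(N - length(h))))
    am <- Mod((stats::fft(X * (Mod(H)^2 * u), inverse = TRUE) / N)[seq_len(n)])
    if (k_smooth > 1) am <- runmean_shrink(am, k_smooth)
    out[b, ] <- am^2
  }
  out
}

#' Measure the onset ITPC of a synthetic dataset at its delta frequency
#'
#' Recovery helper tying the generator to the phase metrics: filters the
#' neural trace in the delta band around the configured reset frequency,
#' epochs at the true anticipatory onsets, and returns the
#' (bias-corrected) ITPC at t = 0 together with the population value
#' [expected_itpc_from_kappa()] implied by the generating concentration.
#'
#' @param dataset A [generate_dataset()] result.
#' @param debias Apply the small-sample ITPC bias correction (recommended;
#'   the uncorrected estimate has positive bias ~ `sqrt(pi / (4 n))`).
#' @return A list with `itpc_onset`, `expected`, `n_trials`.
#' @export
measure_onset_itpc <- function(dataset, debias = TRUE) {
  stopifnot(inherits(dataset, "synth_dataset"))
  cfg <- dataset$truth$config
  x <- dataset$neural
  x <- (x - mean(x)) / stats::sd(x)
  f0 <- cfg$delta_freq_hz
  lo <- max(f0 - 0.5, f0 / 3)
  bank <- tibble::tibble(freq = f0, bw = 1, lo = lo, hi = f0 + 0.5,
                         order_s = 3 / lo)
  class(bank) <- c("filter_bank", class(bank))
  onsets <- dataset$truth$breaths$onset_s[dataset$truth$breaths$is_trial]
  tensor <- suppressMessages(
    epoch_tensor(x, dataset$fs, bank, onsets, window = c(-1, 1),
                 smooth_ms = 0))
  ti <- which.min(abs(tensor$time_s))
  phases <- tensor$phase[, 1, ti]
  list(itpc_onset = itpc(phases, debias = debias),
       expected = expected_itpc_from_kappa(cfg$reset_kappa),
       n_trials = length(phases))
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>\n")
  n_sub <- nrow(x$subject_scalars)
  cat(sprintf("  %d subjects; %d pooled anticipatory trials\n",
              n_sub, x$itpc_combined$anticipatory$n_trials))
  cat(sprintf("  combined anticipatory max ITPC %.3f (%d significant bins); nonanticipatory %.3f (%d)\n",
              max(x$itpc_combined$anticipatory$itpc),
              sum(x$itpc_combined$anticipatory$sig_mask),
              max(x$itpc_combined$nonanticipatory$itpc),
              sum(x$itpc_combined$nonanticipatory$sig_mask)))
  cat(sprintf("  bootstraps: DMP-by-accuracy p = %.3g; accuracy-by-DMP p = %.3g\n",
              x$boot_dmp_by_accuracy$p_percent,
              x$boot_accuracy_by_dmp$p_percent))
  invisible(x)
}

#' One-paragraph textual summary of a results bundle
#'
#' @param bundle A [run_pipeline()] result.
#' @return A character vector of report lines (also printed).
#' @export
summarize_results <- function(bundle) {
  stopifnot(inherits(bundle, "results_bundle"))
  pre_sig <- sum(bundle$pre_power_zmap$fdr_mask)
  post_sig <- sum(bundle$post_power_zmap$fdr_mask)
  it <- bundle$paired[bundle$paired$measure == "itpc_pre", ]
  lines <- c(
    sprintf("Subjects: %d", nrow(bundle$subject_scalars)),
    sprintf("Pre-inhale ITPC, anticipatory vs nonanticipatory: t(%d) = %.2f, p = %.3g",
            it$df, it$t, it$p),
    sprintf("Combined anticipatory map: %d significant bins (FDR q = %g); nonanticipatory: %d",
            sum(bundle$itpc_combined$anticipatory$sig_mask),
            bundle$itpc_combined$anticipatory$fdr_q,
            sum(bundle$itpc_combined$nonanticipatory$sig_mask)),
    sprintf("Pre-inhale power difference: %d significant bins; post-inhale: %d",
            pre_sig, post_sig),
    sprintf("DMP-by-accuracy bootstrap p = %.3g; accuracy-by-DMP bootstrap p = %.3g",
            bundle$boot_dmp_by_accuracy$p_percent,
            bundle$boot_accuracy_by_dmp$p_percent),
    sprintf("Median-split inhale peak (small vs large DMP): t(%d) = %.2f, p = %.3g",
            bundle$median_split$test$df, bundle$median_split$test$t,
            bundle$median_split$test$p))
  cat(lines, sep = "\n")
  invisible(lines)
}
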
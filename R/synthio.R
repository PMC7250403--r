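#' Configuration for the synthetic LFP + respiration generator
#'
#' Bundles and validates every parameter of [generate_dataset()]. Defaults
#' are the package's reference study conditions: ~3 s breathing period, cued
#' trials every 8 breaths (so intertrial gaps exceed 6 respiratory periods),
#' a delta-band oscillation whose phase at anticipatory inhale onsets is von
#' Mises concentrated, respiration-locked theta bursts whose amplitude grows
#' with phase alignment, and behavioral accuracy that decays logistically
#' with the trial's deviation from the mean phase.
#'
#' @param sampling_rate_hz Sampling rate of both traces (Hz).
#' @param duration_s Total recording duration in seconds, or `NULL` to let
#'   the generator size the recording to fit all requested events. A supplied
#'   duration too short to pack the events triggers an error.
#' @param n_anticipatory,n_nonanticipatory Number of cued (odor-anticipating)
#'   and intertrial (nonanticipatory) inhale events to label.
#' @param breath_period_s Nominal respiratory period (s); individual breath
#'   periods are jittered by `breath_jitter` (uniform, fraction of period).
#' @param breath_jitter Fractional period jitter (default 0.15).
#' @param breaths_per_trial Breaths per trial cycle; trials recur every this
#'   many breaths, so the intertrial gap is `breaths_per_trial - 1` periods.
#'   Must be >= 8 when nonanticipatory events are requested, keeping the gap
#'   above 6 respiratory periods.
#' @param delta_freq_hz Frequency of the resettable slow oscillation (Hz,
#'   in \[0.5, 2\]).
#' @param delta_amp Amplitude of the slow oscillation (units of noise SD).
#' @param reset_kappa von Mises concentration of the delta phase realized at
#'   anticipatory inhale onsets; 0 yields uniform onset phases. A
#'   respiration-locked reset occurs at every inhale, but nonanticipatory
#'   onset phases are always drawn uniformly, so anticipation changes only
#'   the phase concentration -- never the power -- of the oscillation.
#' @param reset_mean_phase_rad Preferred onset phase (rad, in (-pi, pi\]).
#' @param reset_lead_s Time before the anticipatory onset at which the
#'   oscillator's phase is reset; the drawn phase is pinned so the realized
#'   phase *at* the onset equals the draw.
#' @param reset_hold_s Time after onset for which the pinned (diffusion-free)
#'   phase trajectory is held before free evolution resumes continuously.
#' @param reset_slew_s Duration of the transition into each reset: an
#'   equal-power amplitude crossfade from the free-running tone onto the
#'   pinned tone. Both components stay at the delta frequency, so the reset
#'   adds no sideband or broadband power (a hard phase jump would inject a
#'   spectral click; a phase slew would frequency-modulate the tone).
#' @param phase_diffusion Phase-diffusion rate of the free-running oscillator
#'   (rad per sqrt(s)). Kept small by default: accumulated breath-timing
#'   jitter already decorrelates nonanticipatory onset phases, and strong
#'   diffusion would broaden the oscillation's spectral line, creating a
#'   power difference between pinned (anticipatory) and free segments.
#' @param theta_freq_hz Frequency of the post-inhale theta burst (Hz, \[4, 8\]).
#' @param theta_base Burst amplitude on anticipatory (odor) inhales before
#'   phase-alignment gain.
#' @param theta_base_nonant Burst amplitude on all other inhales.
#' @param theta_gain Coupling of anticipatory burst amplitude to phase
#'   alignment: amplitude = `theta_base * (1 + theta_gain * cos(phase error))`,
#'   floored at zero.
#' @param accuracy_slope Logistic slope of P(correct) on the trial's true
#'   deviation from the mean phase (rad^-1); 0 decouples behavior from phase.
#' @param accuracy_intercept Logistic intercept; the default gives ~80%
#'   overall accuracy at the default `reset_kappa`.
#' @param inhale_peak_anticipatory,inhale_peak_nonanticipatory Mean inhale
#'   peak airflow per condition (arbitrary units).
#' @param inhale_duration_anticipatory_s,inhale_duration_nonanticipatory_s
#'   Mean inhale duration per condition (s).
#' @param inhale_cv Coefficient of variation of per-breath peak and duration.
#' @param noise_exponent Spectral exponent alpha of the 1/f^alpha background.
#' @param noise_sd Background noise standard deviation.
#' @param resp_noise_sd Sensor noise added to the airflow trace (raw units).
#' @param hardware_highpass_hz Optional first-order causal high-pass applied
#'   to the airflow trace (0 disables; clinical systems often impose
#'   0.08 Hz). Note a causal high-pass shifts zero-crossings slightly.
#' @param trial_pre_s,trial_post_s Extent of the trial (cue) window before
#'   and after the anticipatory inhale onset, used for event labeling.
#' @param seed Integer seed; mandatory. Identical configurations produce
#'   bit-identical datasets.
#'
#' @return An object of class `synth_config` (a validated named list).
#' @seealso [generate_dataset()], [expected_itpc_from_kappa()]
#' @export
synth_config <- function(sampling_rate_hz = 500,
                         duration_s = NULL,
                         n_anticipatory = 20,
                         n_nonanticipatory = 20,
                         breath_period_s = 3,
                         breath_jitter = 0.15,
                         breaths_per_trial = 8,
                         delta_freq_hz = 1,
                         delta_amp = 1.5,
                         reset_kappa = 4,
                         reset_mean_phase_rad = 0,
                         reset_lead_s = 0.5,
                         reset_hold_s = 1,
                         reset_slew_s = 1,
                         phase_diffusion = 0.3,
                         theta_freq_hz = 6,
                         theta_base = 1,
                         theta_base_nonant = 0.2,
                         theta_gain = 0.5,
                         accuracy_slope = 2,
                         accuracy_intercept = 2.2,
                         inhale_peak_anticipatory = 1.5,
                         inhale_peak_nonanticipatory = 1.0,
                         inhale_duration_anticipatory_s = 1.3,
                         inhale_duration_nonanticipatory_s = 1.0,
                         inhale_cv = 0.1,
                         noise_exponent = 1.5,
                         noise_sd = 1,
                         resp_noise_sd = 0.005,
                         hardware_highpass_hz = 0,
                         trial_pre_s = 2,
                         trial_post_s = 2,
                         seed) {
  if (missing(seed)) abort("`seed` is mandatory in synth_config().")
  check_scalar(seed, "seed", integerish = TRUE)
  check_scalar(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  check_scalar(n_anticipatory, "n_anticipatory", lower = 1, integerish = TRUE)
  check_scalar(n_nonanticipatory, "n_nonanticipatory", lower = 0,
               integerish = TRUE)
  check_scalar(breath_period_s, "breath_period_s", lower = 1e-9)
  check_scalar(breath_jitter, "breath_jitter", lower = 0, upper = 0.5)
  check_scalar(breaths_per_trial, "breaths_per_trial", lower = 2,
               integerish = TRUE)
  check_scalar(delta_freq_hz, "delta_freq_hz", lower = 0.5, upper = 2)
  check_scalar(delta_amp, "delta_amp", lower = 0)
  check_scalar(reset_kappa, "reset_kappa", lower = 0)
  check_scalar(reset_mean_phase_rad, "reset_mean_phase_rad",
               lower = -pi, upper = pi)
  check_scalar(reset_lead_s, "reset_lead_s", lower = 0)
  check_scalar(reset_hold_s, "reset_hold_s", lower = 0)
  check_scalar(reset_slew_s, "reset_slew_s", lower = 0)
  check_scalar(phase_diffusion, "phase_diffusion", lower = 0)
  check_scalar(theta_freq_hz, "theta_freq_hz", lower = 4, upper = 8)
  check_scalar(theta_base, "theta_base", lower = 0)
  check_scalar(theta_base_nonant, "theta_base_nonant", lower = 0)
  check_scalar(theta_gain, "theta_gain", lower = 0)
  check_scalar(accuracy_slope, "accuracy_slope", lower = 0)
  check_scalar(accuracy_intercept, "accuracy_intercept")
  check_scalar(inhale_peak_anticipatory, "inhale_peak_anticipatory",
               lower = 1e-9)
  check_scalar(inhale_peak_nonanticipatory, "inhale_peak_nonanticipatory",
               lower = 1e-9)
  check_scalar(inhale_duration_anticipatory_s,
               "inhale_duration_anticipatory_s", lower = 1e-9)
  check_scalar(inhale_duration_nonanticipatory_s,
               "inhale_duration_nonanticipatory_s", lower = 1e-9)
  check_scalar(inhale_cv, "inhale_cv", lower = 0, upper = 0.5)
  check_scalar(noise_exponent, "noise_exponent")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(resp_noise_sd, "resp_noise_sd", lower = 0)
  check_scalar(hardware_highpass_hz, "hardware_highpass_hz", lower = 0)
  check_scalar(trial_pre_s, "trial_pre_s", lower = 0)
  check_scalar(trial_post_s, "trial_post_s", lower = 0)
  if (!is.null(duration_s)) check_scalar(duration_s, "duration_s",
                                         lower = 1e-9)
  if (n_nonanticipatory > 0 && breaths_per_trial < 8) {
    abort(paste0(
      "With nonanticipatory events requested, `breaths_per_trial` must be ",
      ">= 8 so intertrial gaps exceed 6 respiratory periods."))
  }
  max_dur <- inhale_duration_anticipatory_s * (1 + 3 * inhale_cv)
  if (max_dur >= breath_period_s * (1 - breath_jitter)) {
    abort("Inhale durations do not fit inside the jittered breath period.")
  }
  if (reset_slew_s + reset_lead_s + reset_hold_s >=
      breath_period_s * (1 - breath_jitter)) {
    abort(paste0("reset_slew_s + reset_lead_s + reset_hold_s must fit ",
                 "inside one (jittered) breath period."))
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  fs = %g Hz, events: %d anticipatory / %d nonanticipatory\n",
              x$sampling_rate_hz, x$n_anticipatory, x$n_nonanticipatory))
  cat(sprintf("  breath period %g s (trials every %d breaths)\n",
              x$breath_period_s, x$breaths_per_trial))
  cat(sprintf("  delta %g Hz, kappa = %g, mean phase = %g rad\n",
              x$delta_freq_hz, x$reset_kappa, x$reset_mean_phase_rad))
  cat(sprintf("  theta %g Hz (gain %g), accuracy slope %g, seed %d\n",
              x$theta_freq_hz, x$theta_gain, x$accuracy_slope, x$seed))
  invisible(x)
}

#' Population mean resultant length of a von Mises sample
#'
#' For phases drawn from a von Mises distribution with concentration
#' `kappa`, the population value of the inter-trial phase coherence (mean
#' resultant length) is the Bessel-function ratio I1(kappa) / I0(kappa).
#' This is the calibration oracle for phase-reset recovery tests: a dataset
#' generated with concentration `kappa` should yield a measured onset ITPC
#' near this value.
#'
#' @param kappa Nonnegative, finite von Mises concentration (vectorized).
#' @return Numeric in \[0, 1): the expected mean resultant length.
#' @examples
#' expected_itpc_from_kappa(c(0, 2, 5))
#' @export
expected_itpc_from_kappa <- function(kappa) {
  if (!is.numeric(kappa) || any(!is.finite(kappa))) {
    abort("`kappa` must be finite and numeric.")
  }
  if (any(kappa < 0)) abort("`kappa` must be nonnegative.")
  # exponentially scaled Bessel ratio is stable for large kappa
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

# -- internal pieces of the generator ---------------------------------------

# Breath plan: jittered onsets, per-breath inhale peak/duration, trial flags.
plan_breaths <- function(cfg) {
  n_cycles <- cfg$n_anticipatory
  n_breaths <- n_cycles * cfg$breaths_per_trial
  periods <- cfg$breath_period_s *
    (1 + cfg$breath_jitter * stats::runif(n_breaths, -1, 1))
  lead_in <- 5
  onsets <- lead_in + c(0, cumsum(periods[-n_breaths]))
  fs <- cfg$sampling_rate_hz
  onsets <- round(onsets * fs) / fs        # snap to the sample grid
  is_trial <- (seq_len(n_breaths) - 1L) %% cfg$breaths_per_trial == 0L
  jit <- function(n) pmax(1 - 3 * cfg$inhale_cv,
                          1 + cfg$inhale_cv * stats::rnorm(n))
  peak <- ifelse(is_trial, cfg$inhale_peak_anticipatory,
                 cfg$inhale_peak_nonanticipatory) * jit(n_breaths)
  dur <- ifelse(is_trial, cfg$inhale_duration_anticipatory_s,
                cfg$inhale_duration_nonanticipatory_s) * jit(n_breaths)
  dur <- pmin(dur, periods * 0.6)
  tibble::tibble(breath = seq_len(n_breaths), onset_s = onsets,
                 period_s = periods, is_trial = is_trial,
                 inhale_peak = peak, inhale_duration_s = dur)
}

# Airflow waveform: half-sine inhale, area-balanced gamma-shaped exhale that
# approaches zero from below, so every inhale onset is a clean upward
# zero-crossing preceded by sub-zero signal.
build_airflow <- function(breaths, n, fs, resp_noise_sd) {
  x <- numeric(n)
  t0 <- breaths$onset_s[1]
  x[seq_len(max(1L, round(t0 * fs)))] <- -0.1 * mean(breaths$inhale_peak)
  for (j in seq_len(nrow(breaths))) {
    on <- breaths$onset_s[j]
    d <- breaths$inhale_duration_s[j]
    p <- breaths$inhale_peak[j]
    P <- breaths$period_s[j]
    i0 <- round(on * fs) + 1L
    i1 <- min(i0 + round(d * fs) - 1L, n)
    if (i0 > n) break
    s <- (seq(i0, i1) - i0) / fs
    x[i0:i1] <- p * sin(pi * s / d)
    # exhale: -E * (u/tau) * exp(1 - u/tau); E balances the inhale area
    e0 <- i1 + 1L
    e1 <- if (j < nrow(breaths)) round(breaths$onset_s[j + 1] * fs) else n
    if (e0 > n) break
    e1 <- min(e1, n)
    tau <- (P - d) / 4
    gam <- 1 - (1 + 4) * exp(-4)
    E <- (2 * p * d / pi) / (tau * exp(1) * gam)
    u <- (seq(e0, e1) - e0 + 1L) / fs
    x[e0:e1] <- -E * (u / tau) * exp(1 - u / tau)
  }
  if (resp_noise_sd > 0) x <- x + stats::rnorm(n, sd = resp_noise_sd)
  x
}

# Delta oscillator with (mild) phase diffusion, pinned to a drawn target
# phase around EVERY inhale onset (reset_lead_s before to reset_hold_s
# after), resuming free evolution continuously afterwards. Anticipation
# controls only the concentration of the drawn target (von Mises vs
# uniform), so the spectral signature of the reset transitions is
# identically distributed across conditions and resetting produces no
# power difference. Each transition is an equal-power amplitude crossfade
# from the free-running tone onto the pinned tone over reset_slew_s: both
# components oscillate at the delta frequency, so the reset adds no
# sideband or broadband power (a hard phase jump would inject a spectral
# click, and slewing the phase would frequency-modulate the tone), and the
# cross-term is zero-mean across trials.
build_delta_phase <- function(cfg, n, trial_onsets, theta_star) {
  fs <- cfg$sampling_rate_hz
  dt <- 1 / fs
  omega <- 2 * pi * cfg$delta_freq_hz
  dphi <- omega * dt +
    cfg$phase_diffusion * sqrt(dt) * stats::rnorm(n)
  phi_free <- cumsum(dphi) + stats::runif(1, -pi, pi)
  phi <- phi_free
  tt <- (seq_len(n) - 1L) / fs
  nt <- round(cfg$reset_slew_s * fs)
  slews <- vector("list", length(trial_onsets))
  for (k in seq_along(trial_onsets)) {
    on <- trial_onsets[k]
    i0 <- max(1L, round((on - cfg$reset_lead_s) * fs) + 1L)
    i1 <- min(n, round((on + cfg$reset_hold_s) * fs) + 1L)
    if (nt > 0 && i0 > 1L) {
      s0 <- max(1L, i0 - nt)
      slew <- s0:(i0 - 1L)
      u <- seq_along(slew) / (length(slew) + 1L)
      slews[[k]] <- list(
        idx = slew,
        value = cos(u * pi / 2) * cos(phi[slew]) +
          sin(u * pi / 2) * cos(theta_star[k] + omega * (tt[slew] - on)))
    }
    seg <- i0:i1
    phi[seg] <- theta_star[k] + omega * (tt[seg] - on)
    if (i1 < n) {
      offset <- phi[i1] - phi_free[i1]
      nxt <- if (k < length(trial_onsets)) {
        min(n, round((trial_onsets[k + 1] - cfg$reset_lead_s) * fs))
      } else n
      if (i1 + 1L <= nxt) {
        idx <- (i1 + 1L):nxt
        phi[idx] <- phi_free[idx] + offset
      }
    }
  }
  sig <- cos(phi)
  for (sl in slews) {
    if (!is.null(sl)) sig[sl$idx] <- sl$value
  }
  list(phi = phi, sig = sig)
}

# Post-inhale theta bursts: Hann-windowed tone from 0.2 to 1.2 s after each
# inhale onset, random carrier phase per breath.
build_theta <- function(cfg, n, breaths, amp) {
  fs <- cfg$sampling_rate_hz
  x <- numeric(n)
  burst_len <- round(1 * fs)
  env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = burst_len)))
  for (j in seq_len(nrow(breaths))) {
    if (amp[j] <= 0) next
    i0 <- round((breaths$onset_s[j] + 0.2) * fs) + 1L
    i1 <- min(i0 + burst_len - 1L, n)
    if (i0 > n) break
    m <- i1 - i0 + 1L
    s <- (seq_len(m) - 1L) / fs
    psi <- stats::runif(1, -pi, pi)
    x[i0:i1] <- x[i0:i1] +
      amp[j] * env[seq_len(m)] * cos(2 * pi * cfg$theta_freq_hz * s + psi)
  }
  x
}

#' Generate a coupled synthetic LFP + respiration + behavior dataset
#'
#' Simulates one subject's recording with the statistical structure the
#' phase-reset analysis assumes: a 1/f background, a slow (delta-band)
#' oscillation whose phase at anticipatory inhale onsets follows a von Mises
#' law with concentration `reset_kappa`, post-inhale theta bursts whose
#' amplitude on odor trials grows with phase alignment, and trial accuracy
#' whose probability decays logistically with the trial's true deviation
#' from the mean phase (DMP). Ground truth (realized onset phases, true DMP,
#' drawn breath metrics) is returned so recovery tests can compare estimates
#' against it.
#'
#' @param config A [synth_config()].
#' @return An object of class `synth_dataset`: a list with elements
#'   `neural` (numeric trace), `fs`, `respiration` (a [resp_trace()]),
#'   `events` (tibble: `subject`, `onset_s`, `condition`, `correct`,
#'   `inhale_peak`, `inhale_duration_s`), `trial_windows` (tibble with
#'   `start`, `end`), `truth` (list: the `config` plus a per-breath tibble
#'   with realized onset phases and true DMP) and `duration_s`.
#' @examples
#' ds <- generate_dataset(synth_config(
#'   sampling_rate_hz = 100, n_anticipatory = 4, n_nonanticipatory = 4,
#'   seed = 1))
#' ds$events
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config")) {
    abort("`config` must be created by synth_config().")
  }
  cfg <- config
  fs <- cfg$sampling_rate_hz
  withr::with_seed(cfg$seed, {
    breaths <- plan_breaths(cfg)
    need_s <- max(breaths$onset_s) + breaths$period_s[nrow(breaths)] + 5
    dur <- cfg$duration_s %||% need_s
    if (dur < need_s) {
      abort(sprintf(
        "`duration_s` = %g s cannot pack %d trial cycles (needs >= %.1f s).",
        dur, cfg$n_anticipatory, need_s))
    }
    n <- round(dur * fs)

    airflow <- build_airflow(breaths, n, fs, cfg$resp_noise_sd)
    if (cfg$hardware_highpass_hz > 0) {
      airflow <- highpass_first_order(airflow, fs, cfg$hardware_highpass_hz)
    }

    # a respiration-locked reset occurs at every inhale; anticipation
    # changes only the concentration of the drawn onset phase
    theta_all <- wrap_angle(stats::runif(nrow(breaths), -pi, pi))
    theta_all[breaths$is_trial] <-
      rvonmises(sum(breaths$is_trial), cfg$reset_mean_phase_rad,
                cfg$reset_kappa)
    delta <- build_delta_phase(cfg, n, breaths$onset_s, theta_all)

    onset_phase <- theta_all

    dmp_true <- abs(circ_dist(onset_phase, cfg$reset_mean_phase_rad))
    amp <- ifelse(
      breaths$is_trial,
      pmax(0, cfg$theta_base *
             (1 + cfg$theta_gain *
                cos(onset_phase - cfg$reset_mean_phase_rad))),
      cfg$theta_base_nonant)
    theta_sig <- build_theta(cfg, n, breaths, amp)

    neural <- cfg$noise_sd * colored_noise(n, fs, cfg$noise_exponent) +
      cfg$delta_amp * delta$sig + theta_sig

    p_correct <- stats::plogis(cfg$accuracy_intercept -
                                 cfg$accuracy_slope * dmp_true)
    correct <- rep(NA, nrow(breaths))
    correct[breaths$is_trial] <-
      stats::rbinom(sum(breaths$is_trial), 1,
                    p_correct[breaths$is_trial]) == 1

    trial_onsets <- breaths$onset_s[breaths$is_trial]
    trial_windows <- tibble::tibble(start = trial_onsets - cfg$trial_pre_s,
                                    end = trial_onsets + cfg$trial_post_s)

    # eligible nonanticipatory breaths: outside every window by > 2 s guard
    guard <- 2
    near_window <- vapply(breaths$onset_s, function(on) {
      any(on >= trial_windows$start - guard & on < trial_windows$end + guard)
    }, logical(1))
    eligible <- which(!breaths$is_trial & !near_window &
                        breaths$onset_s + 3 < dur & breaths$onset_s > 1.5)
    if (length(eligible) < cfg$n_nonanticipatory) {
      abort(sprintf(
        "Only %d breaths eligible as nonanticipatory events (%d requested).",
        length(eligible), cfg$n_nonanticipatory))
    }
    nonant <- sort(sample(eligible, cfg$n_nonanticipatory))

    truth_tbl <- breaths |>
      dplyr::mutate(
        condition = dplyr::case_when(
          .data$is_trial ~ "anticipatory",
          .data$breath %in% nonant ~ "nonanticipatory",
          TRUE ~ NA_character_),
        onset_phase_rad = onset_phase,
        dmp_true = dmp_true,
        correct = correct)

    events <- truth_tbl |>
      dplyr::filter(!is.na(.data$condition)) |>
      dplyr::transmute(subject = 1L, onset_s = .data$onset_s,
                       condition = .data$condition, correct = .data$correct,
                       inhale_peak = .data$inhale_peak,
                       inhale_duration_s = .data$inhale_duration_s)

    structure(list(
      neural = neural,
      fs = fs,
      respiration = resp_trace(airflow, fs),
      events = events,
      trial_windows = trial_windows,
      truth = list(config = cfg, breaths = truth_tbl),
      duration_s = n / fs
    ), class = "synth_dataset")
  })
}

# causal first-order RC high-pass (models acquisition hardware)
highpass_first_order <- function(x, fs, fc) {
  rc <- 1 / (2 * pi * fc)
  alpha <- rc / (rc + 1 / fs)
  dx <- c(x[1], diff(x))
  as.numeric(stats::filter(alpha * dx, alpha, method = "recursive"))
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("<synth_dataset>\n")
  cat(sprintf("  %.1f s at %g Hz; %d anticipatory / %d nonanticipatory events\n",
              x$duration_s, x$fs,
              sum(x$events$condition == "anticipatory"),
              sum(x$events$condition == "nonanticipatory")))
  cat(sprintf("  reset kappa = %g at %g Hz; seed %d\n",
              x$truth$config$reset_kappa, x$truth$config$delta_freq_hz,
              x$truth$config$seed))
  invisible(x)
}
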
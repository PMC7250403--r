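# Shared fixtures: fast generator configurations and hand-built tensors.

# Small, fast dataset: low rate, no nonanticipatory pool, tight packing.
quick_cfg <- function(seed, n_anticipatory = 50, reset_kappa = 5,
                      sampling_rate_hz = 200, ...) {
  synth_config(sampling_rate_hz = sampling_rate_hz,
               n_anticipatory = n_anticipatory,
               n_nonanticipatory = 0,
               breaths_per_trial = 4,
               reset_kappa = reset_kappa,
               seed = seed, ...)
}

# Build a pa_tensor directly from a phase array (trial x freq x time).
fake_tensor <- function(phase, freq = NULL, time_s = NULL, labels = NULL,
                        amplitude = NULL) {
  d <- dim(phase)
  structure(list(
    phase = phase,
    amplitude = amplitude %||% array(1, d),
    freq = freq %||% seq_len(d[2]),
    time_s = time_s %||% ((seq_len(d[3]) - 1) / 100),
    fs = 100, labels = labels, n_dropped = 0L
  ), class = "pa_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built ITPC map for windowed-maximum tests.
fake_itpc_map <- function(itpc, freq, time_s, n_trials = 10) {
  structure(list(itpc = itpc, rayleigh_z = n_trials * itpc^2,
                 rayleigh_p = matrix(1, nrow(itpc), ncol(itpc)),
                 sig_mask = matrix(FALSE, nrow(itpc), ncol(itpc)),
                 freq = freq, time_s = time_s, n_trials = n_trials,
                 fdr_q = 0.05),
            class = "itpc_map")
}
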
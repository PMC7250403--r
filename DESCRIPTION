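Package: respitpc
Title: Respiration-Locked Phase Reset Analysis for Intracranial LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying anticipatory phase resetting of low-frequency
    local field potential oscillations around nasal inhalation. Provides a
    synthetic generator of coupled iEEG, nasal-airflow and behavioral data with
    von Mises phase-reset structure; airflow normalization and inhale-onset
    detection; a log-spaced zero-phase FIR filter bank with Hilbert phase and
    amplitude extraction; inter-trial phase coherence (phase-locking value)
    maps with Rayleigh tests and FDR correction; the single-trial
    deviation-from-mean-phase statistic; surrogate-event and label-shuffle
    permutation z-maps; bootstrap analyses linking phase alignment to
    perceptual accuracy; and an end-to-end pipeline over simulated cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
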
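---
title: "Quantifying anticipatory phase reset in respiration-locked LFP recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anticipatory phase reset in respiration-locked LFP recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respitpc)
```

## The scientific question

In olfaction, the stimulus arrives when the subject inhales, so the nasal
inhale onset doubles as the stimulus onset. When a subject *anticipates* an
odor -- a cued trial, as opposed to ordinary breathing between trials -- the
phase of slow (delta-band, roughly 0.5-2 Hz) oscillations in olfactory
cortex can re-align to the upcoming inhale before it begins. `respitpc`
implements the full analysis chain needed to detect and characterize such
anticipatory phase resetting from a single intracranial channel plus a
synchronized nasal-airflow trace:

1. airflow normalization, inhale-onset detection, condition labeling and
   equal-N subsampling (`normalize_trace()`, `detect_inhale_onsets()`,
   `label_events()`, `subsample_nonanticipatory()`);
2. a log-spaced zero-phase FIR filter bank with Hilbert phase/amplitude
   extraction and inhale-aligned epoching (`make_filter_bank()`,
   `epoch_tensor()`);
3. inter-trial phase coherence (ITPC) maps with Rayleigh tests and FDR
   correction, windowed maxima, Rayleigh-z time courses, and the
   single-trial deviation-from-mean-phase statistic (`itpc_map()`,
   `max_itpc()`, `rayleigh_z_timeseries()`, `compute_dmp()`);
4. power controls and permutation statistics (`welch_psd()`, `power_map()`,
   `label_shuffle_zmap()`, `surrogate_event_zmap()`), bootstrap analyses
   linking phase alignment to perceptual accuracy
   (`bootstrap_dmp_by_accuracy()`, `bootstrap_accuracy_by_dmp()`), paired
   tests, a 2x2 repeated-measures ANOVA and median-split analyses;
5. an orchestrated pipeline over whole cohorts (`run_pipeline()`).

Because clinical iEEG of this kind is rarely shareable, the package's primary
input is its own synthetic generator, which is first-class, tested code --
not a fixture. Everything below about the generator therefore doubles as the
definition of the conditions under which the package's claims are tested.

## The statistics

**ITPC / phase-locking value.** For phases $\varphi_j$ across $n$ trials at
one time-frequency bin,
$$\mathrm{ITPC} = \Big|\tfrac1n \sum_{j=1}^n e^{i\varphi_j}\Big| \in [0, 1],$$
0 for no clustering, 1 for perfect clustering. Its significance is assessed
with the Rayleigh test, $z = nR^2$ with
$p = \exp\{\sqrt{1 + 4n + 4(n^2 - (nR)^2)} - (1 + 2n)\}$, and
Benjamini-Hochberg FDR across all bins of a map (Benjamini-Yekutieli is
available via `fdr_method`).

Uniform phases still give $E[R] \approx \sqrt{\pi/(4n)}$, a pure
sampling bias. Where a *population* concentration must be estimated -- the
recovery analyses that compare measured ITPC against the generator's ground
truth -- the package uses the standard debiased estimate
$\sqrt{\max(R^2 - 1/n,\, 0)}$ (`itpc(..., debias = TRUE)`), which is
centered at 0 under uniformity. Maps and significance tests use the plain
estimate, as is conventional.

**DMP (deviation from the mean phase).** A single-trial index of reset: at
inhale onset, at the frequency where onset ITPC peaks within 0.5-2 Hz, each
trial's DMP is its unsigned circular distance to the circular mean phase,
in $[0, \pi]$. Small DMP = well-aligned trial. The unsigned convention is
forced by the downstream grouping into "most-" and "least-aligned" trials.
If the resultant length at onset is numerically zero the mean phase is
undefined and `compute_dmp()` raises an error rather than guessing.

**Resampling statistics.** Three p-values accompany each bootstrap
difference distribution: the *percentage-based* p (the fraction of
repetitions failing the hypothesized direction; exact zeros count against
it, and a value of 0 is displayed as "< 1/n_boot" rather than as a literal
zero), a normal-approximation p from $z = \bar d / s_d$, and an exact
binomial sign-test p. The bootstrap resample size equals the original group
size (the standard bootstrap; configurable), a choice the source analyses
leave open. Surrogate-event nulls shift every event independently by a
uniform random amount, circular over the recording with a minimum shift of
one epoch length: per-event shifts destroy event locking while preserving
the marginal signal statistics. Label-shuffle nulls re-partition pooled
epochs preserving group sizes.

## The synthetic generator

`generate_dataset(synth_config(...))` simulates one subject:

* **Respiration** -- half-sine inhales with per-breath jittered periods
  (+-15% by default) and an area-balanced, gamma-shaped exhale that
  approaches zero from below, so every inhale onset is a clean upward
  zero-crossing of the zero-referenced airflow (as from a pressure
  transducer). Inhale peak and duration means are condition-dependent.
  An optional first-order 0.08 Hz causal high-pass models acquisition
  hardware; it is off by default because a causal high-pass shifts
  zero-crossings slightly, and the generator's contract places onsets
  within one sample of a crossing.
* **Background** -- spectrally shaped Gaussian noise with a $1/f^{1.5}$
  spectrum, matching the featureless PSD of olfactory cortex (no theta
  peak).
* **Delta oscillation and reset** -- a tone at `delta_freq_hz` (default
  1 Hz, amplitude 1.5 noise-SD units) with mild phase diffusion. A
  respiration-locked reset occurs at *every* inhale: the oscillator's
  phase is pinned, from `reset_lead_s` (0.5 s) before the onset to
  `reset_hold_s` (1 s) after it, to a drawn target phase. Anticipatory
  inhales draw from a von Mises law with concentration `reset_kappa`
  (default 4) around `reset_mean_phase_rad`; all other inhales draw
  uniformly. Anticipation therefore changes only the *concentration* of
  the onset phase, never the energy of the signal. The transition onto
  each pinned segment is an equal-power amplitude crossfade
  (`reset_slew_s`, 1 s) between the free-running and pinned tones: both
  components oscillate at the delta frequency, so the reset adds no
  sideband or broadband power. This matters: a hard phase jump injects a
  spectral click, and slewing the phase itself frequency-modulates the
  tone by up to `jump / (2 pi T)` Hz -- both produce condition-locked
  power artifacts in the pre-inhale window that the modeled phenomenon
  (reset without power change) must not have. A band-limited oscillation
  cannot reset both instantaneously and silently; the crossfade trades a
  gradual coherence build-up (starting ~1.5 s before onset, saturating
  0.5 s before) for spectral neutrality, which is the trade the data this
  emulates appear to make.
* **Why the reset leads the onset.** The drawn phase is realized *at* the
  onset, but the pinning starts `reset_lead_s` before it. If the reset
  happened exactly at t = 0, the band-pass filter (seconds long at delta
  frequencies) would mix pre-reset, uniformly distributed phase into the
  onset estimate and the measured ITPC could not approach the population
  value $I_1(\kappa)/I_0(\kappa)$ -- the generator would fail its own
  recovery contract. Anticipatory alignment beginning shortly before the
  inhale is also the phenomenon itself.
* **Theta response** -- each inhale is followed by a Hann-windowed theta
  burst (0.2-1.2 s after onset, random carrier phase). On odor trials its
  amplitude is `theta_base * (1 + theta_gain * cos(phase error))`, coupling
  the evoked response to the quality of the reset; other inhales get a
  small baseline burst (`theta_base_nonant`).
* **Behavior** -- trial accuracy is Bernoulli with
  $P(\mathrm{correct}) = \mathrm{logistic}(\mathrm{intercept} -
  \mathrm{slope}\cdot \mathrm{DMP}_{\mathrm{true}})$; the default
  intercept 2.2 yields ~80% overall accuracy at the default concentration,
  keeping both accuracy groups populated. Inhale peaks and durations are
  drawn independently of phase alignment, so the motor pathway is null by
  construction.
* **Trial structure** -- cued trials recur every 8 breaths, so intertrial
  gaps exceed 6 respiratory periods (the inclusion criterion for a clean
  anticipatory/nonanticipatory distinction); nonanticipatory events are
  drawn from breaths at least 2 s outside every cue window.

The ground truth (`$truth`) stores the realized onset phase and true DMP of
every breath, so recovery tests compare estimates against truth rather than
against other estimates.

What the generator does *not* emulate: multi-electrode volume conduction,
epileptiform artifacts, non-stationary breathing rates, odorant chemistry,
or any coupling between respiration depth and neural amplitude. Passing
tests on synthetic cohorts demonstrates that the estimators recover the
structure they target at realistic SNR and trial counts -- not that real
piriform recordings contain that structure.

## Numerical choices

* **Filter bank** -- 50 log-spaced centers, 0.5-200 Hz, bandwidths
  log-increasing 1 to 2 Hz; windowed-sinc (Hamming) FIR kernels spanning 3
  cycles of the band's low edge (a control mode uses 2 cycles of the
  center frequency). Low edges at or below 0 Hz are clipped to one third
  of the center frequency, with a warning. Filters are applied
  forward-backward; the implementation multiplies by the squared magnitude
  response in the frequency domain, which is the two-pass filter computed
  in O(n log n) -- direct convolution with multi-second kernels over
  minutes of signal would be orders of magnitude slower. The fused
  filter-Hilbert-epoch path is tested to agree with the composed
  individual operations.
* **Phase convention** -- radians in $(-\pi, \pi]$, 0 at the cosine peak;
  epochs are half-open sample windows $[t_0 + w_0, t_0 + w_1)$ with the
  onset sample at t = 0; at 500 Hz a (-1 s, 3 s) window has exactly 2000
  samples.
* **Amplitude smoothing** -- 10 ms centered moving average with shrinking
  edge windows (full-kernel mean preservation holds for interior-supported
  signals; exact global mean preservation is impossible with shrinking
  edges).
* **dB convention** -- 10 log10 of power; baseline correction subtracts
  the per-frequency mean dB over the 1 s pre-onset window; pre-inhale
  power is deliberately *not* baseline-corrected (baseline division alters
  signal-to-noise and hence phase estimates).
* **Welch PSD** -- Hann tapers, 50% overlap, zero-padded to a 0.05 Hz
  grid; the taper length adapts down to the segment length for the 1 s
  pre-inhale windows.
* **Ties** -- windowed ITPC maxima break ties to the lowest frequency,
  then earliest time; Spearman correlations use average ranks; the median
  trial is excluded from odd-count median splits.
* **Degenerate inputs** -- zero-variance traces, all-zero signals,
  undefined circular means, empty groups and incomplete ANOVA designs all
  raise errors naming the violated precondition rather than returning
  NaN.

## Pipeline and problem sizes

`run_pipeline(analysis_config(...))` runs, in order: respiration processing
and event labeling (re-deriving events from the airflow rather than
trusting the generator's table), preprocessing, spectral decomposition,
per-subject and pooled ITPC maps, power controls, DMP and bootstrap
analyses, correlations, the 2x2 ANOVA (anticipatory-state x time-window,
on windowed ITPC maxima over [-1, -0.5] s and [-0.5, 0] s), and the
median-split motor control. Every stage seed derives deterministically from
the master seed; rerunning a configuration reproduces all numeric tables
bit-identically. Both combined (pooled-trial) and per-subject analyses are
always produced; pooling across subjects is simple concatenation of trials
after per-subject normalization, without stratifying the Rayleigh test by
subject -- a documented simplification.

The package's reference cohort for end-to-end checks is 13 simulated
subjects, 20 anticipatory plus 20 nonanticipatory events each, generated
and analyzed at 250 Hz with a 20-band 0.5-30 Hz bank, 200 permutations and
1000 bootstrap repetitions. These sizes were chosen as the smallest cohort
at which all the structure the generator plants (reset cluster, theta
difference, accuracy coupling, null motor link) is comfortably recoverable;
the estimators themselves default to the full 50-band, 0.5-200 Hz, 500 Hz
configuration.

```{r cohort, eval = FALSE}
cfg <- analysis_config(n_subjects = 13, seed = 1,
                       synth = list(sampling_rate_hz = 250))
bundle <- run_pipeline(cfg)
summarize_results(bundle)
autoplot(bundle$itpc_combined$anticipatory)
```

## Known limitations

* Single-channel only: the common-average reference degenerates to mean
  removal, and no spatial analyses are attempted.
* The generator realizes a *true reset* of the ongoing oscillation. An
  additive evoked component phase-locked to the inhale could produce
  similar ITPC signatures; the data this package emulates cannot fully
  distinguish the two mechanisms, and neither can the package.
* The combined analysis pools trials across subjects without stratification,
  so a single high-concentration subject can dominate a small cohort.
* Temporal leakage is bounded, not absent: with 2-cycle kernels, energy
  within the measured band that starts after t = 0 still smears backward
  by about one kernel length. The leakage control is therefore informative
  for responses outside the delta band (e.g. theta bursts), not for
  hypothetical post-onset delta transients.
* The percentage-based p-value has resolution 1/n_boot and is reported as
  an inequality at that resolution, never as 0.
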
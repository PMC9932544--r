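---
title: "Alpha-state-indexed analysis of speech-evoked FFRs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-state-indexed analysis of speech-evoked FFRs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question and the measurement model

The frequency-following response (FFR) is a sustained scalp potential
phase-locked to the periodicity of a sound. For speech tokens with a voice
fundamental (F0) of 150 Hz the response is dominated by subcortical
generators, because 150 Hz exceeds the phase-locking limit of cortical
neurons. `alphaFFR` implements an analysis of *online cortical-brainstem
interplay*: trials of speech-evoked EEG are split by the concurrent
parieto-occipital alpha (8-12 Hz) power — a running index of cortical arousal
state — and the brainstem source FFR is compared between low- and high-alpha
states. The central statistic is the within-participant **F0 ratio**,

$$ \mathrm{F0\ ratio} = \frac{\mathrm{F0\ amp}_{\mathrm{high}\,\alpha}}
                             {\mathrm{F0\ amp}_{\mathrm{low}\,\alpha}}, $$

which exceeds 1 when the brainstem response is stronger during high cortical
alpha. Downstream, alpha-indexed F0 amplitudes are related to behavior
(QuickSiN SNR-loss, pure-tone average, target-detection accuracy and reaction
time) through Spearman correlations, dummy-coded slope-contrast regressions,
and a permutation-validated SVM classification of perceptual performance from
FFR spectra.

Because no recorded cohort is distributed with the analysis, the package
carries a first-class synthetic-data module that generates sessions, cohorts,
and behavior with the statistical structure the analysis assumes and with
known ground truth, so every stage can be tested by parameter recovery.

## Signal chain and its fixed conventions

The analysis chain is: re-reference → resample to 5 kHz → band split →
epoch → alpha indexing → leadfield pseudo-inverse source transform →
category averaging → steady-state spectrum → F0 ratio. Each stage has a
small number of pinned conventions:

* **Analysis sampling rate, 5 kHz.** The band-pass filter lengths the
  procedure is defined by (661 taps / 0.132 s for 100-1,000 Hz; 8,251 taps /
  1.65 s for 8-12 Hz) are mutually consistent only at a 5 kHz rate, although
  acquisition runs at 20 kHz. The pipeline therefore contains an explicit
  integer-decimation resampling stage (zero-phase windowed-sinc anti-alias
  low-pass, cutoff 0.44 × target rate), and all filter design happens at
  5 kHz.
* **FIR design rule.** Band-pass filters are windowed-sinc designs (Hamming
  window; 0.02 dB nominal passband ripple, 53 dB stopband attenuation)
  with automatic transition bandwidths `min(max(0.25 * edge, 2 Hz), margin)`
  and length `ceil(3.3 / min(transition) * fs)` forced odd; the ideal
  impulse response is placed at the −6 dB cutoffs, half a transition width
  outside the band edges. This is the unique convention reproducing all
  printed values (661; 8,251; −6 dB cutoffs 7 and 13.5 Hz). Filters are
  applied zero-phase (group delay `(n_taps − 1)/2` removed) so FFR latencies
  are undistorted. Note the rule's floor binds only for edges at or below
  8 Hz: an 18-22 Hz band gets transition widths 4.5/5.5 Hz, hence −6 dB
  cutoffs 15.75/24.75 Hz.
* **References.** Sensor-level (alpha/beta/control) streams are re-referenced
  to linked mastoids (TP9/TP10); source analysis uses a common average
  reference, and the leadfield columns are average-referenced before
  pseudo-inversion so that the inversion is exact for average-referenced
  data.
* **Epochs.** 195 ms windows, −50 to +145 ms around frequent-token onsets
  under a half-open `[−50, 145)` convention: 975 samples at 5 kHz, onset at
  1-based sample 251. The convention is a choice (the window's inclusivity
  is not otherwise determined); it is fixed here because the downstream
  450-sample steady-state segment and 226-bin spectrum depend on it. Rare
  /ta/ targets are excluded from neural analysis; trials whose window
  exceeds the recording are dropped, never padded (padding would bias RMS).
* **Alpha indexing.** Per-trial RMS of the POz proxy (mean of Pz and Oz) in
  8-12 Hz, normalized to each run's median (so each run's normalized median
  is exactly 1), then categorized within participant × condition: at or
  below the 35th percentile = "low", at or above the 65th = "high", middle
  30% excluded from averaging. Quantiles are type-7 (linear interpolation);
  boundary ties go to the extreme class and are trimmed back by trial index
  (earliest kept, low resolved before high). With 6,000 frequent trials this
  yields exactly 2,100 trials per extreme category. The same machinery runs
  unchanged on the POz beta (18-22 Hz) and Fz alpha control streams.
* **Spectra.** The steady-state 10-100 ms portion (half-open; 450 samples)
  of each category average is Blackman-tapered and transformed without
  zero-padding: 226 one-sided bins at 5000/450 = 11.1 Hz. Amplitudes are
  normalized by the taper's coherent gain so a unit sinusoid at a bin
  centre reads ≈ 1. The F0 amplitude is the maximum over the grid bins
  whose coverage interval (centre ± half spacing) overlaps 150 ± 5.5 Hz;
  on the 11.1 Hz grid these are the two bins flanking 150 Hz (the bin
  *centres* lie at 144.44 and 155.56 Hz, fractionally outside the nominal
  interval, so a centre-inclusion rule would select nothing — the coverage
  rule is the reading that makes the search well-defined). The response SNR
  is `20·log10(F0 amplitude / noise floor)` with the noise floor defined —
  a choice this package fixes — as the mean amplitude over flanking bins
  with centres in 150 ± [22, 55] Hz; category averages under 3 dB are
  flagged, not dropped.

## The synthetic-data generator

`simulate_session()` generates what the pipeline assumes and nothing more:

* A brainstem z-oriented source emits a phase-locked burst 10-100 ms after
  every token onset: 150 Hz plus two harmonics (relative amplitudes
  1/0.4/0.2) with 5 ms raised-cosine ramps. The burst is polarity-invariant
  (envelope-following), so alternating-polarity trials average coherently —
  token acoustics themselves are never synthesized because the pipeline
  never touches audio.
* Trial amplitude is `ffr_gain × (1 + g × (α_state − 1))`, where `α_state`
  is the generated alpha envelope normalized to its session median and `g`
  (`coupling`) is the ground-truth driver of the F0 ratio. The paradigm the
  generator emulates reports the alpha-FFR relation as a *finding*, not a
  generative model, so `g` is this package's construct; no external value
  constrains its scale. Group defaults (NH coupled for clear speech, weakly
  in noise; HL uncoupled for clear speech, coupled in noise) mirror the
  qualitative result pattern the analysis is designed to detect.
* A posterior alpha source (10 Hz carrier, slow amplitude modulation from
  linearly interpolated 0.5 s knots, depth `alpha_mod_depth`) is projected
  to parieto-occipital channels; NH listeners draw larger alpha amplitudes
  than HL listeners.
* Sensor noise per channel is white noise plus a band-limited low-frequency
  drift (content below ~7 Hz) standing in for the 1/f part of the EEG
  spectrum. The drift is deliberately kept below the alpha band's lower
  cutoff so that it perturbs but does not swamp single-trial alpha RMS.
  `noise_sd` is referenced to the 20 kHz acquisition rate (i.e. it fixes a
  spectral density), so synthesizing at 5 kHz gives the same statistics as
  acquiring at 20 kHz and resampling. The default (2 µV at 20 kHz) is
  chosen so that scaled-down category averages (tens of trials) sit in the
  same "robust response, ≥ 3 dB SNR" regime that full-scale ~2,100-trial
  averages occupy in real recordings; single-trial SNR is accordingly more
  favourable than real EEG, which is what makes parameter recovery testable
  at tractable problem sizes.
* The noise condition adds a 100-1,000 Hz Gaussian masker to the evoked
  source drive at −10 dB relative amplitude and scales the FFR gain by
  `noise_ffr_scale` (default 0.85): a degraded-response regime, not a
  realistic babble model.
* The leadfield is a smooth 32-channel model with the z column maximal along
  the fronto-central vertex line (mimicking the predominantly vertical
  current flow of the auditory midbrain); any user leadfield (channels × 3
  CSV) can replace it. No BEM/FEM head modelling is attempted.
* Behavior: per-target hit probability is a logistic function of `ffr_gain`
  and mean RT falls with hit probability from a 250 ms floor (negative
  accuracy-RT dependence in the clear condition, weakened in noise);
  QuickSiN keyword tallies are binomial draws from a logistic psychometric
  function whose SNR-50 tracks PTA, scored by the Spearman-Kärber rule
  (SNR-50 = 27.5 − total keywords correct; SNR-loss = SNR-50 − 2 dB,
  averaged over four lists). These links reproduce sign structure, not any
  particular effect size.

What passing tests on this generator do **not** show: robustness to
artifacts (ocular/muscle), realistic 1/f and alpha non-stationarity, real
head geometry, or acoustic-level effects. The generator is a correctness
harness for the pipeline's algebra and statistics, not a forward model of
real EEG.

## Statistics

The statistical battery delegates test internals to standard routines and
owns the wiring: one-sample t of F0 ratios against 1; Mann-Whitney U group
comparisons with Bonferroni bookkeeping (`p_adj = min(1, m·p)`); paired
Wilcoxon for raw F0 amplitudes (identical pairs give W = 0, p = 1 by
convention); an equal-variance F test reported with the larger variance in
the numerator; Conover-Iman rank-based post-hoc pairwise tests (implemented
in-package from the standard formula, as no installed package provides
them); a 2 × 2 × 2 (SNR × alpha × group) mixed ANOVA on log F0 amplitudes
with participants as the random factor, computed through classical `aov()`
error strata, with partial eta squared `SS_effect/(SS_effect + SS_error)`
per stratum, followed by within-group 2 × 2 ANOVAs; Spearman brain-behavior
correlations with Shapiro-Wilk screens logged as rationale; and the
dummy-coded regressions

$$ Y = \beta_0 + \beta_1 X + \beta_2\,\mathrm{group} +
       \beta_3\,X\cdot\mathrm{group}\ (+\ \beta_4\,\mathrm{age}), $$

with NH coded 0 and HL 1 so `β1` is the NH slope, `β1 + β3` the HL slope and
`β3` the slope difference, gated on residual diagnostics (Shapiro-Wilk,
Breusch-Pagan, and Goldfeld-Quandt with the split at the median of X and
the central 20% omitted — the split convention is fixed here for
determinism). All tests are two-sided.

## Classification

Perceptual performance levels come from clear-condition percent-correct
scores: poor ≤ 30th percentile, good ≥ 70th (type-7 quantiles; boundary
ties enter the extreme class then trim to the percentile share; all-equal
scores refuse classification). Poor/good participants' 226-bin FFR spectra
feed a radial-basis SVM (C = 1,000, gamma by the "scale" convention
`1/(226 · var(X_train))`, no feature standardization — raw amplitudes are
deliberately fed as-is). One iteration = one stratified 4-fold split with
the minority class randomly oversampled *inside the training portion only*;
fold accuracies are averaged. The published procedure runs N = 5,000
iterations; the iteration count is a free parameter here. Significance uses
a feature-shuffle null — each null iteration independently permutes the 226
values within every participant's row, a fresh shuffle per iteration (the
more conservative reading of the procedure) — and the empirical p-value
`p = (a + 1)/(n + 1)`, with `a` counting null accuracies *strictly* above
the median of the actual distribution.

One calibration subtlety: with a single fixed random label assignment, the
cross-validated accuracy median of a 20-participant cohort is itself a
widely dispersed random variable (spurious structure in one feature draw
moves it by ±0.15), so "centred at 0.5" is only a well-defined claim when
labels are re-assigned independently on every iteration. The package's
calibration tests therefore permute labels per iteration for the centring
check, and use the full fixed-label actual/shuffled-feature null procedure
for the p-value validity check. A small pessimistic offset of the median
below 0.50 is expected: cross-validation on label-free data is mildly
anti-conservative in accuracy terms, a known small-sample artifact.

## Problem sizes used by the tests

The full paradigm (3,000 + 3,000 + 210 tokens per condition, 32 channels,
20 kHz) implies ~7 GB per session and is never materialized. The package's
tests run the identical code on proportionally shortened token trains:

* end-to-end acquisition-rate check: 400 frequent tokens at 20 kHz,
  resampled to 5 kHz;
* coupling recovery: 5 couplings (0-0.8) × 20 seeds at 250-token sessions,
  plus 50 no-coupling seeds at 400-token sessions (sized so the mean's
  standard error, ~0.006, resolves the [0.98, 1.02] null band), synthesized
  at the 5 kHz analysis rate (`noise_sd`'s density referencing makes this
  statistically equivalent to 20 kHz synthesis plus resampling, which is
  itself verified separately);
* trial-categorization at full scale (6,000 frequent tokens) on the
  single-stream alpha chain, which is the only part trial counts depend on;
* classifier calibration: 50 replications of N = 80 iterations (actual and
  null) for the p-value validity check — the bound P(p ≤ 0.05) ≤ 0.07 is
  assessed by a one-sided binomial test at this replication count, since a
  point-estimate comparison would be dominated by binomial noise whenever
  the underlying rate sits near the bound — plus 600 label-permutation
  iterations for the centring check.

These sizes were chosen so the complete suite runs in tens of minutes on
one CPU while every assertion remains a property of the full-scale
procedure (counts, conventions, monotonicity, calibration) rather than of
the reduced size.

## Known limitations

* The leadfield is supplied, not fitted; dipole fitting and multi-source
  montages are out of scope, as are x/y source orientations.
* The generator's behavior links are monotone and noiseless in structure;
  they support sign-level assertions only.
* Span lengths of alpha states are reported, not asserted against any
  particular value: they are a property of the data, not of the method.
* Printed cohort statistics of the paradigm this package operationalizes
  (group t/U values, specific correlation magnitudes, classifier medians)
  are data-dependent and are not reproduction targets; the package
  reproduces the *procedure* exactly and validates it by parameter recovery
  on synthetic ground truth.

## A worked mini-run

```{r, eval = FALSE}
library(alphaFFR)

cohort <- make_cohort(n_nh = 2, n_hl = 2, seed = 7)
run <- run_pipeline(cohort,
                    stimulus = stimulus_spec(n_ba = 100, n_pa = 100, n_ta = 7),
                    acquisition_fs = 5000, seed = 8)
run$f0_table[, c("id", "group", "condition", "f0_ratio", "snr_low_db")]
report <- ffr_report(run)
report$f0_ratio_tests
```
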
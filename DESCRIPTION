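Package: alphaFFR
Title: Alpha-State-Indexed Analysis of Speech-Evoked Frequency-Following Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study real-time cortical-brainstem interplay during
    speech perception from multichannel EEG. Trials of speech-evoked activity
    are split by concurrent parieto-occipital alpha (8-12 Hz) power, brainstem
    source frequency-following responses (FFRs) are derived per alpha state via
    a leadfield pseudo-inverse spatial filter, and the F0-ratio modulation
    statistic (high-alpha over low-alpha F0 amplitude) is computed from
    Blackman-windowed steady-state spectra. Includes a synthetic-cohort
    generator with programmable alpha-FFR coupling and known ground truth, the
    accompanying statistical battery (one-sample tests on F0 ratios,
    non-parametric group comparisons, mixed ANOVA on log F0 amplitudes,
    brain-behavior correlations, and dummy-coded slope-contrast regressions
    with residual diagnostics), QuickSiN and target-detection behavior scoring,
    and a permutation-validated radial-basis SVM classifier of perceptual
    performance from FFR spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    e1071,
    lmtest,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
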
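Package: eegemotion
Title: Frontal Asymmetry and Midline Power Analysis of Discrete Emotions from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discriminating discrete emotions that are close in
    the valence-arousal plane from multichannel EEG. Provides a synthetic
    film-viewing cohort generator with planted band- and channel-group-specific
    amplitude effects, band-pass filtering and epoch-based artifact rejection,
    Hanning-tapered short-time Fourier band-power estimation with eyes-open
    baseline normalization, frontal-asymmetry and midline-power feature
    construction, a statistical battery (paired t with effect sizes, chi-square
    frequency test, 2x2 within-subject univariate and multivariate interaction
    tests, partial correlation with Benjamini-Hochberg correction, p-value
    driven stepwise regression), and sparse-LDA-ranked support vector machine
    classification under leave-one-subject-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
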
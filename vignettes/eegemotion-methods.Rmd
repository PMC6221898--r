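---
title: "Methods: band power, frontal asymmetry, and emotion classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band power, frontal asymmetry, and emotion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegemotion)
```

## The problem

Two discrete emotions can occupy nearly the same point in the
valence-arousal plane — amusement and tenderness are both pleasant and
moderately arousing; anger and fear are both unpleasant and highly
arousing — yet correspond to different cortical states. `eegemotion`
implements an EEG analysis chain for separating such pairs using two
feature families that valence/arousal models ignore: *frontal asymmetry*
(right-minus-left band power at homologous prefrontal pairs FP1/FP2 and
F3/F4, where alpha power is inversely related to regional activation) and
*midline power* (theta/alpha/beta power at the sagittal sites FZ, FCZ, CZ,
CPZ, PZ). The package covers the whole chain: a synthetic film-viewing
cohort generator, preprocessing and band-power estimation, feature
construction, a statistical battery, and subject-independent
classification.

Because no raw recordings ship with the package, every stage is exercised
on the synthetic cohort, whose planted effects have known direction and
size. Results on synthetic data validate the *machinery* — recovery of
planted directions, calibration, error control — not any empirical claim
about real brains.

## Band power and baseline normalization

Each recording is band-pass filtered to 1–35 Hz (cascaded Butterworth
high-pass order 4 and low-pass order 5, each applied forward–backward for
zero phase; the cascade keeps sections low-order and stable at a 1-Hz edge
with a 500-Hz rate, and the two-sided pass doubles the effective order).
Epochs of 2 s with 50% overlap are Hanning-tapered; epochs whose absolute
voltage exceeds a threshold (default 100 µV, per-subject configurable) are
rejected. Per-bin power is window-power compensated — divided by
`n * sum(w^2)` with one-sided doubling — so that the sum of bin powers
equals the signal variance (Parseval). Band power is the *mean* over the
bins of the half-open interval `[lo, hi)`, so 8 Hz belongs to alpha only
and 13 Hz to beta only; the `n_bins` column converts means back to band
totals. Film-clip power is computed over artifact-free epochs only, and
the manifest records this choice.

Condition power is then normalized per subject, condition and band by the
scalar

$$\hat P_C(e, f) = \frac{P_C(e, f)}{\frac1N \sum_{e'=1}^{N} P_B(e', f)},$$

where the denominator averages the *eyes-open baseline preceding that
film* over the `N` scalp electrodes of the active layout (`N = 31` for the
default montage; the value used is recorded in the output). Because the
denominator does not depend on the electrode, topography is preserved,
inter-individual scale differences divide out, and any multiplicative
carry-over from the previous film is referenced away.

**Numerical properties worth knowing.** A 2-s Hanning window has a
main-lobe width of about one 0.5-Hz bin on each side, so spectral content
within ~0.5 Hz of a band edge is partially assigned to the neighboring
band. For an isolated narrow band this biases the band total low by
roughly 5%; when adjacent bands carry comparable spectral density the
exchange is nearly symmetric and the bias largely cancels. It also cancels
in every analysis the pipeline reports, which compare the *same* band
across conditions or divide it by the *same* band at baseline. The
calibration test therefore plants a flat 1–35 Hz spectrum, where each
band is recovered within 5%; the white-noise test checks that band totals
scale with bandwidth (theta:beta = 4:17).

## The synthetic cohort

`generate_cohort()` emulates the study conditions: 33 subjects, four film
conditions (amusement, tenderness, anger, fear), one 40-s eyes-open
baseline before each 60-s film, 31-channel 10/20 montage, 500 Hz. Each
channel is a sum of band-limited components built by inverse-FFT spectrum
shaping — flat magnitude across the band's bins, independent uniform
random phases — scaled so the component's sample variance is exactly
`a^2/2` for amplitude `a` (the sinusoid convention), plus a broadband
Gaussian noise floor (default SD 1 µV). Spectrum shaping was chosen over
sums of sinusoids because it gives exactly controllable band variance with
realistic within-band spread. Between-subject heterogeneity is a per-band
log-normal amplitude factor (log-SD 0.3), multiplicative because absolute
EEG power is strictly positive and right-skewed. Default band amplitudes
(theta 6, alpha 8, beta 4 µV) follow the usual resting ordering of scalp
rhythms.

Planted condition effects multiply amplitudes for (condition,
channel-group, band) triples. The defaults encode only the *directions*
the pipeline is designed to detect — tenderness > amusement in
right-frontal theta/alpha and midline alpha/beta; fear > anger in
right-frontal and midline theta — each with amplitude factor 1.3. The
magnitude is a free parameter of the generator, not an empirical claim.
Ratings are rounded, clipped Gaussians on the 1–9 scale with per-condition
means/SDs matching the published subjective-assessment table; the target
emotion's intensity is forced at least one point above every non-target
intensity by default, reproducing a 100% hit rate. Baselines carry no
condition effect, so the subject factor cancels in normalization and the
planted normalized effect at an affected electrode is approximately the
squared amplitude factor.

What the generator does **not** emulate: volume conduction and channel
covariance (channels are independent given their amplitudes), ocular/EMG
artifacts, event-related dynamics within a film, non-stationarity, or any
distributional model fitted to real EEG (none is published). Passing tests
therefore demonstrate correct recovery of planted structure, not
performance on real recordings; published real-data effect sizes and
accuracies are explicitly out of scope.

## The statistical battery

* **Paired t** on subject-wise differences, two-sided, `df = n - 1`.
  Published paired designs report standardized effects under at least two
  conventions that disagree numerically, so the package reports both
  `d_z = mean(d)/sd(d)` (default) and `d_av = mean(d)/((sd(x)+sd(y))/2)`.
  Degenerate inputs are defined: all-equal pairs give `t = 0, p = 1`; zero
  difference variance with a nonzero mean gives `t = ±Inf, p = 0`.
  `paired_t_from_summary()` reconstructs `t` from a printed difference
  mean/SD.
* **Chi-square goodness of fit** `sum((O-E)^2/E)` with `df = k - 1`.
* **2×2 within-subject interaction**: the per-subject double difference
  `g_i = (A1B1 - A1B2) - (A2B1 - A2B2)` reduces the interaction to a
  one-sample test — `F = t^2` on `(1, n-1)` df with partial eta squared
  `t^2/(t^2 + n - 1)`. Sphericity corrections are vacuous for two-level
  factors and are therefore not implemented. The multivariate version
  applies one-sample Hotelling `T^2` to the double-difference vectors of
  `p` dependent variables, with `Wilks λ = 1/(1 + T^2/(n-1))` and
  `F = ((n-p)/p) T^2/(n-1)` on `(p, n-p)` df; a singular contrast
  covariance is an error, and identically-zero contrasts return
  `T^2 = 0, λ = 1` by convention.
* **Partial correlation**: Pearson correlation of least-squares residuals
  after projecting both variables on the covariates plus intercept, with
  `df = n - k - 2`; families of such tests are corrected by
  Benjamini–Hochberg step-up FDR (`bh_fdr()`, backed by `p.adjust`). The
  step-up rule guarantees adjusted ≥ raw and monotonicity, but it is not
  idempotent on arbitrary already-adjusted vectors — only flat vectors are
  fixed points — so the test suite checks the properties that actually
  hold.
* **Stepwise regression** by partial-F p-values: forward entry of the
  smallest entry p below `p_enter`, backward removal above `p_remove`,
  iterated to stability with a `4 × #candidates` iteration guard.
  Thresholds default to 0.05/0.10, the conventional defaults of common
  commercial statistics software, since no thresholds are published;
  `p_enter > p_remove` is rejected at input validation because it can
  cycle. Reports unstandardized `B` with SEs, standardized `β`, adjusted
  `R²`, and the overall F. (The base-R `step()` selects by AIC, which is a
  different rule, hence the bespoke implementation.)

`stats_report()` assembles the full battery in the layout of the study:
interaction tests at FP1/FP2, F3/F4 and the composites
`F_left = (FP1+F3)/2`, `F_right = (FP2+F4)/2`; midline paired t per band
and site for both emotion pairs; a stepwise regression of each film's
target rating on the 19 asymmetry+midline features; and partial
correlations of liking and dominance with those features controlling
arousal, valence and familiarity, BH-corrected per family. Bonferroni
multiplication for simple effects uses family size 2 (two simple effects
per interaction), configurable, as no family size is published.

## Feature sets and classification

Five feature sets are assembled from normalized powers (normalized is the
default; absolute powers are a switch, since the published description
does not say which entered the classifier): the whole-scalp set of 75
features (3 bands × 25 non-midline electrodes — the published electrode
list names 26 labels including PZ, a midline site; the package uses the 26
minus PZ so that 3 × 25 = 75 holds and midline features stay disjoint),
that set plus 15 midline powers (90), plus 4 frontal asymmetries (79),
plus all 19 (94), and the 19 new features alone.

Feature ranking uses sparse linear discriminant analysis via
elastic-net-penalized optimal scoring: alternate between solving the
penalized regression of scored class indicators on standardized features
(glmnet; L1 weight `sparsity = 1e-3`, ridge `1e-2` by default — published
penalty magnitudes are unavailable, so both are exposed as configuration)
and updating the class scores under D-orthogonality to previously found
directions. The K−1 sparse discriminant vectors zero out many
coefficients; surviving features are ranked by the maximum absolute
coefficient across vectors, ties broken by column order for
reproducibility. As the L1 weight vanishes on well-conditioned two-class
data the leading direction converges to the classical Fisher LDA
direction, which the test suite verifies.

Classification is leave-one-subject-out: for each fold, feature
standardization and the SLDA ranking are fitted on the training subjects
only, the ranked features (all of the nonzero support by default; a fixed
`top_k` is available) feed a soft-margin SVM, and the held-out subject's
instances are predicted. The kernel is linear with cost 1 — a deliberate
choice for the small-n/high-p regime, matching common affective-EEG
practice, since the published kernel is unstated. With one instance per
subject and condition, each binary fold holds out two instances and a
33-subject task yields 66 test instances; no subject exclusions are
implemented. Accuracy on effect-free data sits in the permutation-null
band around chance, and corrupting a held-out subject cannot change the
model of the fold that excludes it (both tested).

## Problem sizes used by the test suite

The suite validates statistical properties at the sizes the checks need,
chosen once as a balance of statistical resolution and runtime: 2,000
replicates for paired-t error rates, 100 seeded replicates for SLDA
ranking, 60 label permutations for the LOSO null, 20 seeded cohorts
(33 subjects, 128 Hz, 30-s films) for the feature-set comparison, 300
simulated subjects for the planted-asymmetry direction check, and one
default-scale pipeline run (33 subjects, 500 Hz, 60-s films). Reduced
sampling rates keep band content identical (all bands lie far below
either Nyquist limit); segment durations only widen Monte-Carlo error,
which the acceptance margins already accommodate.

## Known limitations

* Channel independence in the generator means scalp topography carries no
  spatial correlation; classifiers may find synthetic problems easier than
  real ones.
* Band-edge leakage of the 2-s Hanning STFT mixes adjacent bands within
  ~0.5 Hz of each edge (see above); beta estimates next to a strong alpha
  peak inherit part of that peak. This is a property of the published
  analysis parameters, not of the implementation.
* Ocular-artifact handling is amplitude-threshold rejection only; no
  regression or ICA correction is provided, and mastoid re-referencing is
  a no-op on the synthetic montage, which is generated already referenced.
* The stepwise procedure inherits the usual caveats of p-value-driven
  selection (inflated `R²`, unstable selection at small n); it is provided
  because it mirrors the study's analysis, not as a recommendation.
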
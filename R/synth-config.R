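#' Default frequency bands
#'
#' Theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz. Bands are half-open
#' `[lo, hi)`, so 8 Hz belongs to alpha only and 13 Hz to beta only.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
default_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Emotion conditions of the film-viewing paradigm
#' @return Character vector of the four film conditions.
#' @export
emotion_conditions <- function() {
  c("amusement", "tenderness", "anger", "fear")
}

# Per-condition rating distributions: SAM dimensions plus the target DES
# score, as mean (sd) on the 1-9 scale. Non-target DES intensities share one
# weak distribution: films rarely elicit much of a non-target emotion.
default_rating_params <- function() {
  mk <- function(arousal, valence, liking, familiarity, dominance, target) {
    list(arousal = arousal, valence = valence, liking = liking,
         familiarity = familiarity, dominance = dominance, target = target)
  }
  list(
    amusement  = mk(c(5.94, 2.12), c(5.91, 2.37), c(5.14, 2.47),
                    c(2.24, 2.27), c(5.78, 2.23), c(6.84, 2.09)),
    tenderness = mk(c(5.39, 1.52), c(5.30, 1.74), c(5.38, 1.99),
                    c(2.73, 2.42), c(6.51, 1.97), c(7.22, 1.64)),
    anger      = mk(c(7.46, 1.50), c(1.09, 0.29), c(1.49, 1.12),
                    c(2.95, 2.77), c(4.03, 2.40), c(7.70, 1.53)),
    fear       = mk(c(7.30, 1.81), c(1.24, 0.44), c(2.11, 1.70),
                    c(1.24, 0.76), c(3.68, 2.42), c(6.65, 2.36)),
    nontarget  = c(2.0, 1.5)
  )
}

#' Default planted amplitude effects
#'
#' Encodes only the *directions* of the group differences the pipeline is
#' designed to detect, each with amplitude factor `magnitude` (default 1.3):
#' tenderness exceeds amusement in right-frontal theta and alpha and in
#' midline alpha and beta; fear exceeds anger in right-frontal and midline
#' theta. Channel groups are `right_frontal` (FP2, F4) and `midline`.
#'
#' @param magnitude Positive amplitude multiplier applied to every planted
#'   effect.
#' @return A data.frame with columns condition, group, band, multiplier.
#' @export
default_effects <- function(magnitude = 1.3) {
  stopifnot(magnitude > 0)
  eff <- rbind(
    data.frame(condition = "tenderness", group = "right_frontal",
               band = c("theta", "alpha")),
    data.frame(condition = "tenderness", group = "midline",
               band = c("alpha", "beta")),
    data.frame(condition = "fear", group = c("right_frontal", "midline"),
               band = "theta"))
  eff$multiplier <- magnitude
  eff
}

#' Configuration of the synthetic EEG cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: 33 subjects,
#' four emotional film clips each preceded by its own eyes-open baseline,
#' 500 Hz working sampling rate, 60-s films and 40-s baselines. Band
#' amplitudes follow the usual resting posterior-dominant ordering
#' (alpha > theta > beta); between-subject heterogeneity is multiplicative
#' log-normal because absolute EEG power is strictly positive and
#' right-skewed.
#'
#' @param n_subjects Number of subjects (default 33).
#' @param fs Sampling rate in Hz (default 500).
#' @param film_duration_s,baseline_duration_s Segment lengths in seconds
#'   (defaults 60 and 40); both must allow at least one 2-s analysis window.
#' @param bands Named list of half-open `c(lo, hi)` band edges within
#'   \[1, 35\] Hz, non-overlapping.
#' @param base_amplitude Named numeric, per-band RMS-defining amplitude in
#'   microvolts; a band component of amplitude `a` has variance `a^2/2`.
#' @param effects data.frame(condition, group, band, multiplier) of planted
#'   amplitude effects; groups are `right_frontal`, `midline`, or an
#'   electrode label. Conditions absent from the table get multiplier 1.
#' @param subject_sd Log-scale SD of the per-subject, per-band amplitude
#'   factor (default 0.3).
#' @param noise_floor SD in microvolts of the broadband Gaussian noise added
#'   to every channel (default 1).
#' @param rating_params Per-condition rating means/SDs; see
#'   `default_rating_params()` internals.
#' @param force_hit Force each film's target DES score at least one point
#'   above every non-target score (default TRUE, emulating a 100% hit rate).
#' @param layout A `channel_layout`.
#' @param seed Integer seed making the cohort reproducible.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 33,
                         fs = 500,
                         film_duration_s = 60,
                         baseline_duration_s = 40,
                         bands = default_bands(),
                         base_amplitude = c(theta = 6, alpha = 8, beta = 4),
                         effects = default_effects(),
                         subject_sd = 0.3,
                         noise_floor = 1,
                         rating_params = default_rating_params(),
                         force_hit = TRUE,
                         layout = default_layout(),
                         seed = 1L) {
  if (n_subjects < 1) stop("configuration error: n_subjects must be >= 1")
  if (length(layout$names) == 0L) stop("configuration error: empty layout")
  if (film_duration_s < 2 || baseline_duration_s < 2) {
    stop("segment durations must be at least 2 s (one analysis window)")
  }
  edges <- do.call(rbind, bands)
  if (any(edges < 1) || any(edges > 35)) {
    stop("band edges must lie within [1, 35] Hz")
  }
  if (any(edges[, 1] >= edges[, 2])) stop("band lo must be < hi")
  ord <- order(edges[, 1])
  if (any(edges[ord, 2][-nrow(edges)] > edges[ord, 1][-1])) {
    stop("bands must be non-overlapping")
  }
  if (fs <= 2 * max(edges)) {
    stop("fs must exceed twice the highest band edge")
  }
  if (!all(names(bands) %in% names(base_amplitude))) {
    stop("base_amplitude must name every band")
  }
  if (any(base_amplitude < 0)) stop("base_amplitude must be non-negative")
  if (nrow(effects) > 0 && any(effects$multiplier <= 0)) {
    stop("effect multipliers must be positive")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), fs = fs,
         film_duration_s = film_duration_s,
         baseline_duration_s = baseline_duration_s,
         bands = bands, base_amplitude = base_amplitude,
         effects = effects, subject_sd = subject_sd,
         noise_floor = noise_floor, rating_params = rating_params,
         force_hit = force_hit, layout = layout, seed = as.integer(seed)),
    class = "synth_config")
}

# Amplitude multiplier for (condition, electrode, band) under the planted
# effect table. Groups resolve against the layout; unknown = no effect.
effect_multiplier <- function(config, condition, electrode, band) {
  eff <- config$effects
  if (is.null(eff) || nrow(eff) == 0) return(1)
  grp_of <- function(e) {
    g <- character()
    if (e %in% c("FP2", "F4")) g <- c(g, "right_frontal")
    if (e %in% config$layout$midline_set) g <- c(g, "midline")
    c(g, e)
  }
  hits <- eff[eff$condition == condition & eff$band == band &
                eff$group %in% grp_of(electrode), , drop = FALSE]
  if (nrow(hits) == 0) 1 else prod(hits$multiplier)
}
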
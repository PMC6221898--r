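test_that("cohort generation is bit-identical under a fixed seed", {
  sc <- synth_config(n_subjects = 2, fs = 128, film_duration_s = 4,
                     baseline_duration_s = 2, seed = 11)
  a <- generate_cohort(sc)
  b <- generate_cohort(sc)
  expect_identical(a, b)
  # and differs under another seed
  sc2 <- synth_config(n_subjects = 2, fs = 128, film_duration_s = 4,
                      baseline_duration_s = 2, seed = 12)
  expect_false(identical(generate_cohort(sc2)$recordings[[1]]$samples,
                         a$recordings[[1]]$samples))
})

test_that("each subject contributes one baseline and one film per condition", {
  sc <- synth_config(n_subjects = 3, fs = 128, film_duration_s = 4,
                     baseline_duration_s = 2, seed = 5)
  cohort <- generate_cohort(sc)
  expect_length(cohort$recordings, 3 * 8)
  kinds <- table(vapply(cohort$recordings, `[[`, "", "segment_kind"))
  expect_equal(unname(kinds[["film"]]), 12)
  expect_equal(unname(kinds[["baseline_eyes_open"]]), 12)
  expect_equal(nrow(cohort$ratings), 12)
  expect_error(synth_config(n_subjects = 0), "configuration error")
})

test_that("band-limited synthesis hits the planted variance exactly", {
  lay <- one_channel_layout()
  amp <- matrix(c(0, 10, 0), 1, 3,
                dimnames = list("CZ", c("theta", "alpha", "beta")))
  rec <- synthesize_recording(list(subject_id = 1, amplitude = amp),
                              "none", "film", 60, 500, default_bands(),
                              lay, noise_floor = 0)
  v <- stats::var(drop(rec$samples))
  expect_lt(abs(v - 50) / 50, 0.05)           # target a^2/2 = 50
  expect_lt(abs(mean(rec$samples)), 1e-8)
})

test_that("zero amplitude and zero noise give an all-zero recording", {
  lay <- one_channel_layout()
  amp <- matrix(0, 1, 3)
  rec <- synthesize_recording(list(subject_id = 1, amplitude = amp),
                              "none", "film", 2, 128, default_bands(),
                              lay, noise_floor = 0)
  expect_true(all(rec$samples == 0))
  expect_error(synthesize_recording(list(subject_id = 1, amplitude = amp),
                                    "none", "film", 2, 50, default_bands(),
                                    lay), "Nyquist|twice")
})

test_that("independent random phases decorrelate identical channels", {
  lay <- channel_layout(c("C3", "C4"), midline_set = character(),
                        pairs = list())
  amp <- matrix(c(0, 0, 8, 8, 0, 0), 2, 3)
  set.seed(3)
  rs <- replicate(20, {
    rec <- synthesize_recording(list(subject_id = 1, amplitude = amp),
                                "none", "film", 10, 128, default_bands(),
                                lay, noise_floor = 0)
    stats::cor(rec$samples[1, ], rec$samples[2, ])
  })
  expect_lt(abs(mean(rs)), 0.05)
  expect_lt(max(abs(rs)), 0.4)
})

test_that("without planted effects, condition band powers are equal in expectation", {
  sc <- synth_config(n_subjects = 4, fs = 128, film_duration_s = 60,
                     baseline_duration_s = 10, effects = default_effects()[0, ],
                     noise_floor = 0, seed = 21)
  seeds <- subject_seeds(sc)
  ratios <- sapply(seq_len(sc$n_subjects), function(s) {
    subj <- generate_subject(sc, s, seeds[s])
    films <- Filter(function(r) r$segment_kind == "film", subj$recordings)
    bp <- lapply(films[1:2], function(r) {
      band_power(segment_epochs(r), sc$bands)
    })
    bp[[1]]$power[bp[[1]]$band == "alpha" & bp[[1]]$electrode == "CZ"] /
      bp[[2]]$power[bp[[2]]$band == "alpha" & bp[[2]]$electrode == "CZ"]
  })
  expect_lt(max(abs(ratios - 1)), 0.05)
})

test_that("planted-power calibration holds over random configurations", {
  # the generator's calibration contract: the sample variance of a
  # band-limited component equals the planted a^2/2 (100 Monte-Carlo reps
  # over random amplitudes and bands)
  lay <- one_channel_layout()
  set.seed(8)
  err <- replicate(100, {
    a <- stats::runif(1, 2, 12)
    b <- sample(3, 1)
    amp <- matrix(0, 1, 3); amp[1, b] <- a
    rec <- synthesize_recording(list(subject_id = 1, amplitude = amp),
                                "none", "film", 60, 128, default_bands(),
                                lay, noise_floor = 0)
    abs(stats::var(drop(rec$samples)) - a^2 / 2) / (a^2 / 2)
  })
  expect_lt(max(err), 0.05)
})

test_that("band-power estimates track planted power across the spectrum", {
  # estimator calibration on a flat 1-35 Hz planting (band-limited white
  # spectrum, per-component variance proportional to bandwidth): each of
  # the three analysis bands recovered within 5% of planted. A flat
  # spectrum makes the Hanning-window leakage exchange at band edges
  # symmetric, isolating the estimator's own calibration.
  lay <- one_channel_layout()
  bands5 <- c(list(guard_lo = c(1, 4)), default_bands(),
              list(guard_hi = c(30, 35)))
  widths <- vapply(bands5, diff, 0)
  set.seed(18)
  err <- replicate(100, {
    dens <- stats::runif(1, 0.5, 4)              # uV^2 per Hz
    v <- dens * widths
    amp <- matrix(sqrt(2 * v), 1, 5)
    rec <- synthesize_recording(list(subject_id = 1, amplitude = amp),
                                "none", "film", 60, 128, bands5,
                                lay, noise_floor = 0)
    bp <- band_power(segment_epochs(rec), default_bands())
    tot <- bp$power * bp$n_bins
    abs(tot - v[2:4]) / v[2:4]
  })
  expect_lt(max(err), 0.05)
})

test_that("a planted right-frontal alpha effect propagates to the asymmetry", {
  # alpha amplitude x1.5 at FP2/F4 for tenderness only: after the full
  # band-power + baseline-normalization chain, the FP1/FP2 alpha asymmetry
  # is larger for tenderness than for amusement in at least 80% of
  # simulated subjects (300 subjects, 30-s films)
  eff <- data.frame(condition = "tenderness", group = "right_frontal",
                    band = "alpha", multiplier = 1.5)
  sc <- synth_config(n_subjects = 300, fs = 128, film_duration_s = 30,
                     baseline_duration_s = 15, effects = eff, seed = 77)
  seeds <- subject_seeds(sc)
  greater <- vapply(seq_len(sc$n_subjects), function(s) {
    subj <- generate_subject(sc, s, seeds[s])
    keep <- vapply(subj$recordings, function(r) {
      r$condition %in% c("amusement", "tenderness")
    }, TRUE)
    powers <- compute_band_powers(subj$recordings[keep],
                                  filter_band = NULL)
    tab <- baseline_normalize(powers, scalp_set = sc$layout$scalp_set)
    a <- asymmetry(tab, c("FP1", "FP2"), "alpha")
    a$asymmetry[a$condition == "tenderness"] >
      a$asymmetry[a$condition == "amusement"]
  }, TRUE)
  expect_gte(mean(greater), 0.80)
})

test_that("ratings respect the 1-9 scale and the forced hit rate", {
  sc <- synth_config(n_subjects = 8, fs = 128, film_duration_s = 2,
                     baseline_duration_s = 2, seed = 14)
  set.seed(14)
  recs <- do.call(rbind, lapply(emotion_conditions(), function(cc) {
    do.call(rbind, replicate(8, generate_ratings(sc, cc),
                             simplify = FALSE))
  }))
  vals <- as.matrix(recs)
  expect_true(all(vals >= 1 & vals <= 9))
  expect_true(all(vals == round(vals)))
  # forced hit: target at least one above every non-target
  cohort <- generate_cohort(sc)
  for (f in emotion_conditions()) {
    expect_equal(hit_rate(cohort$ratings, f), 1.0)
  }
})

test_that("zero-SD rating parameters reproduce the rounded means", {
  sc <- synth_config(n_subjects = 1, fs = 128, film_duration_s = 2,
                     baseline_duration_s = 2, seed = 1)
  sc$rating_params$anger <- lapply(sc$rating_params$anger,
                                   function(ms) c(ms[1], 0))
  sc$rating_params$nontarget <- c(2.0, 0)
  set.seed(1)
  r <- generate_ratings(sc, "anger")
  expect_equal(r$valence, round(1.09))
  expect_equal(r$arousal, round(7.46))
  expect_equal(r$des_anger, round(7.70))
  expect_equal(r$des_fear, 2)
})

test_that("anger valence draws match the published mean and spread", {
  sc <- synth_config(n_subjects = 1, fs = 128, film_duration_s = 2,
                     baseline_duration_s = 2, seed = 2)
  set.seed(2)
  vals <- replicate(4000, generate_ratings(sc, "anger")$valence)
  expect_lt(abs(mean(vals) - 1.09), 0.05)
  expect_lt(abs(stats::sd(vals) - 0.29), 0.05)
})

test_that("cohort round-trips through the manifest directory format", {
  sc <- synth_config(n_subjects = 1, fs = 128, film_duration_s = 2,
                     baseline_duration_s = 2, seed = 9)
  cohort <- generate_cohort(sc)
  dir <- tempfile("cohort")
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$recordings), length(cohort$recordings))
  expect_equal(back$recordings[[3]]$samples, cohort$recordings[[3]]$samples)
  expect_equal(back$recordings[[3]]$condition,
               cohort$recordings[[3]]$condition)
  expect_equal(back$ratings$des_anger, cohort$ratings$des_anger)
  unlink(dir, recursive = TRUE)
})
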
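make_tone_rec <- function(freq, fs = 500, dur = 20, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  lay <- one_channel_layout()
  structure(
    list(subject_id = 1, segment_kind = "film", condition = "none",
         samples = matrix(amp * sin(2 * pi * freq * t), nrow = 1,
                          dimnames = list("CZ", NULL)),
         fs = fs, layout = lay),
    class = "raw_recording")
}

# amplitude of the central portion, avoiding filter edge transients
mid_amp <- function(rec) {
  n <- ncol(rec$samples)
  keep <- rec$samples[1, floor(n / 4):floor(3 * n / 4)]
  stats::sd(keep) * sqrt(2)
}

test_that("band-pass filter preserves in-band tones and rejects out-of-band", {
  in_band <- bandpass_filter(make_tone_rec(10), 1, 35)
  expect_lt(abs(mid_amp(in_band) - 1), 0.02)

  drift <- bandpass_filter(make_tone_rec(0.2), 1, 35)
  expect_lt(mid_amp(drift), 0.10)

  mains <- bandpass_filter(make_tone_rec(50), 1, 35)
  expect_lt(mid_amp(mains), 0.05)

  expect_error(bandpass_filter(make_tone_rec(10), 35, 1), "invalid band")
  expect_error(bandpass_filter(make_tone_rec(10), 1, 300), "invalid band")
})

test_that("re-referencing subtracts the mastoid mean", {
  lay <- channel_layout(c("C3", "C4", "M1", "M2"),
                        scalp_set = c("C3", "C4"),
                        midline_set = character(), pairs = list(),
                        reference_set = c("M1", "M2"))
  set.seed(1)
  x <- matrix(rnorm(4 * 100), 4, 100, dimnames = list(lay$names, NULL))
  rec <- structure(list(subject_id = 1, segment_kind = "film",
                        condition = "none", samples = x, fs = 100,
                        layout = lay), class = "raw_recording")
  rr <- rereference(rec)
  ref <- colMeans(x[c("M1", "M2"), ])
  expect_equal(rr$samples["C3", ], x["C3", ] - ref)
  # mastoid mean is zero at every sample afterwards
  expect_equal(max(abs(colMeans(rr$samples[c("M1", "M2"), ]))), 0)

  # zero references leave the data unchanged
  x0 <- x; x0[c("M1", "M2"), ] <- 0
  rec0 <- rec; rec0$samples <- x0
  expect_equal(rereference(rec0)$samples["C3", ], x0["C3", ])

  # a channel equal to the reference mean becomes zero
  x1 <- x; x1["C3", ] <- colMeans(x[c("M1", "M2"), ])
  rec1 <- rec; rec1$samples <- x1
  expect_equal(max(abs(rereference(rec1)$samples["C3", ])), 0)

  rec_noref <- make_tone_rec(10)
  expect_warning(out <- rereference(rec_noref), "no reference")
  expect_equal(out$samples, rec_noref$samples)
})

test_that("epoch segmentation yields the documented window counts", {
  rec <- make_tone_rec(10, fs = 100, dur = 60)
  expect_length(segment_epochs(rec, 2, 0.5)$epochs, 59)
  expect_length(segment_epochs(rec, 2, 0)$epochs, 30)
  rec2 <- make_tone_rec(10, fs = 100, dur = 2)
  expect_length(segment_epochs(rec2, 2, 0.5)$epochs, 1)
  expect_error(segment_epochs(rec2, 4), "longer than")
})

test_that("artifact rejection removes exactly the offending epochs", {
  rec <- make_tone_rec(10, fs = 100, dur = 20, amp = 40)  # within +/-50
  es <- segment_epochs(rec, 2, 0)
  expect_length(reject_artifacts(es, 100)$epochs, length(es$epochs))
  expect_equal(reject_artifacts(es, 100)$kept_fraction, 1)

  # plant a 200-uV spike inside the 4th epoch only
  spiked <- rec
  spiked$samples[1, 650] <- 200
  es2 <- segment_epochs(spiked, 2, 0)
  kept <- reject_artifacts(es2, 100)
  expect_length(kept$epochs, length(es2$epochs) - 1)
  expect_equal(kept$kept_fraction, 9 / 10)
  expect_identical(kept$epochs[[4]], es2$epochs[[5]])

  expect_length(reject_artifacts(es2, Inf)$epochs, length(es2$epochs))
  spiked_all <- rec
  spiked_all$samples[1, ] <- 500
  expect_error(reject_artifacts(segment_epochs(spiked_all, 2, 0), 100),
               "all epochs rejected")
})

test_that("band power recovers a sinusoid's total power in its own band", {
  rec <- make_tone_rec(10, fs = 500, dur = 60, amp = 2)
  bp <- band_power(segment_epochs(rec), default_bands())
  alpha_tot <- bp$power[bp$band == "alpha"] * bp$n_bins[bp$band == "alpha"]
  expect_lt(abs(alpha_tot - 2) / 2, 0.05)     # a^2/2 = 2
  expect_lt(bp$power[bp$band == "theta"], 1e-3)
  expect_lt(bp$power[bp$band == "beta"], 1e-3)

  z <- make_tone_rec(10, amp = 0)
  bpz <- band_power(segment_epochs(z), default_bands())
  expect_true(all(bpz$power == 0))

  small <- make_tone_rec(10, fs = 40, dur = 10)
  expect_error(band_power(segment_epochs(small), default_bands()),
               "outside resolvable")
})

test_that("white-noise band totals scale with bandwidth (flat spectrum)", {
  set.seed(4)
  lay <- one_channel_layout()
  ratio <- replicate(30, {
    x <- matrix(rnorm(20 * 500), nrow = 1, dimnames = list("CZ", NULL))
    rec <- structure(list(subject_id = 1, segment_kind = "film",
                          condition = "none", samples = x, fs = 500,
                          layout = lay), class = "raw_recording")
    bp <- band_power(segment_epochs(rec), default_bands())
    tot <- function(b) bp$power[bp$band == b] * bp$n_bins[bp$band == b]
    tot("theta") / tot("beta")
  })
  expect_lt(abs(mean(ratio) - 4 / 17), 0.02)
})

test_that("three-band total cannot exceed the broadband power", {
  sc <- synth_config(n_subjects = 1, fs = 128, film_duration_s = 20,
                     baseline_duration_s = 10, seed = 31)
  subj <- generate_subject(sc, 1, 99)
  rec <- subj$recordings[[2]]
  es <- segment_epochs(rec)
  bp <- band_power(es, sc$bands)
  wide <- band_power(es, list(all = c(1, 35)))
  for (e in rec$layout$names) {
    three <- sum(bp$power[bp$electrode == e] * bp$n_bins[bp$electrode == e])
    total <- wide$power[wide$electrode == e] * wide$n_bins[wide$electrode == e]
    expect_lt(three, total * 1.05)
  }
})

test_that("baseline normalization matches the per-band scalar formula", {
  lay4 <- channel_layout(c("E1", "E2", "E3", "E4"),
                         midline_set = character(), pairs = list())
  film <- data.frame(subject = 1, condition = "amusement",
                     segment_kind = "film",
                     electrode = "E1", band = "theta", power = 2.0)
  base <- data.frame(subject = 1, condition = "amusement",
                     segment_kind = "baseline_eyes_open",
                     electrode = c("E1", "E2", "E3", "E4"), band = "theta",
                     power = c(1, 2, 3, 2))
  out <- baseline_normalize(rbind(film, base), scalp_set = lay4$names)
  expect_equal(out$normalized, 1.0)            # 2 / mean(1,2,3,2)
  expect_equal(attr(out, "n_norm"), 4)

  # P_C equal to the baseline mean -> 1; global rescaling is invariant
  film2 <- film; film2$power <- 42
  base2 <- base; base2$power <- base$power * 21
  out2 <- baseline_normalize(rbind(film2, base2), scalp_set = lay4$names)
  expect_equal(out2$normalized, 1.0)

  c_scale <- 3.7
  out3 <- baseline_normalize(
    rbind(transform(film, power = power * c_scale),
          transform(base, power = power * c_scale)),
    scalp_set = lay4$names)
  expect_equal(out3$normalized, out$normalized)

  base0 <- base; base0$power <- 0
  expect_error(baseline_normalize(rbind(film, base0),
                                  scalp_set = lay4$names), "denominator")
})

test_that("normalization is scale-invariant across the whole cohort table", {
  cc <- cached_cohort_table()
  sc <- cc$config
  cohort_powers <- compute_band_powers(
    generate_subject(sc, 1, subject_seeds(sc)[1])$recordings,
    filter_band = NULL)
  t1 <- baseline_normalize(cohort_powers, scalp_set = sc$layout$scalp_set)
  scaled <- cohort_powers
  scaled$power <- scaled$power * 5.5
  t2 <- baseline_normalize(scaled, scalp_set = sc$layout$scalp_set)
  expect_equal(t2$normalized, t1$normalized)
  expect_equal(t2$absolute, t1$absolute * 5.5)
})
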
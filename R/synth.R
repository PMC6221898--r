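#' Synthesize one multichannel EEG recording
#'
#' Builds each channel as a sum of band-limited components plus a broadband
#' Gaussian noise floor. A band component is made by inverse-FFT spectrum
#' shaping: flat magnitude across the band's frequency bins, independent
#' uniform random phases per bin and channel, scaled so the component's
#' sample variance equals the target `a^2/2` exactly (an amplitude-`a`
#' convention, as for a sinusoid). Channel means are ~0 (DC bin excluded).
#'
#' @param subject_params List with `amplitude`, an electrodes x bands matrix
#'   of per-channel band amplitudes in microvolts (already including subject
#'   factor and any condition effect), as built by [generate_cohort()].
#' @param condition One of [emotion_conditions()] or `"none"` for baselines.
#' @param segment_kind `"film"` or `"baseline_eyes_open"`.
#' @param duration_s Segment length in seconds, at least 2.
#' @param fs Sampling rate, Hz; must exceed twice the highest band edge.
#' @param bands Named list of half-open band edges, as in [default_bands()].
#' @param layout A `channel_layout`.
#' @param noise_floor SD of the additive broadband noise, microvolts.
#'
#' @return A `raw_recording`: list with `subject_id`, `segment_kind`,
#'   `condition`, `samples` (electrodes x time matrix, microvolts, with
#'   electrode rownames), `fs`, `layout`.
#' @export
synthesize_recording <- function(subject_params, condition, segment_kind,
                                 duration_s, fs, bands,
                                 layout = default_layout(),
                                 noise_floor = 0) {
  if (duration_s < 2) stop("duration must be at least 2 s")
  top <- max(vapply(bands, max, 0))
  if (fs <= 2 * top) stop("fs must exceed twice the highest band edge")
  amp <- subject_params$amplitude
  n_ch <- length(layout$names)
  stopifnot(nrow(amp) == n_ch, ncol(amp) == length(bands))
  n <- round(duration_s * fs)
  freqs <- seq(0, fs / 2, by = fs / n)      # rFFT bin frequencies
  x <- matrix(0, nrow = n_ch, ncol = n)
  for (b in seq_along(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    idx <- which(freqs >= lo & freqs < hi & freqs > 0 & freqs < fs / 2)
    if (length(idx) == 0) next
    v <- amp[, b]^2 / 2                     # target variance per channel
    # sample variance of sum of k unit-magnitude rFFT bins is 2k/n^2 per
    # Parseval; scale magnitudes so the realized variance is exactly v
    mag <- n * sqrt(v / (2 * length(idx)))
    spec <- matrix(0 + 0i, nrow = n, ncol = n_ch)
    ph <- matrix(stats::runif(length(idx) * n_ch, 0, 2 * pi),
                 nrow = length(idx))
    spec[idx, ] <- exp(1i * ph) * rep(mag, each = length(idx))
    # conjugate-symmetric negative frequencies -> real signal
    spec[n + 2 - idx, ] <- Conj(spec[idx, ])
    comp <- Re(stats::mvfft(spec, inverse = TRUE)) / n
    x <- x + t(comp)
  }
  if (noise_floor > 0) {
    x <- x + matrix(stats::rnorm(n_ch * n, sd = noise_floor), nrow = n_ch)
  }
  rownames(x) <- layout$names
  structure(
    list(subject_id = subject_params$subject_id,
         segment_kind = segment_kind, condition = condition,
         samples = x, fs = fs, layout = layout),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording> subject ", x$subject_id, ", ", x$segment_kind,
      if (x$condition != "none") paste0(" (", x$condition, ")"),
      ": ", nrow(x$samples), " ch x ", ncol(x$samples), " samples @ ",
      x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Draw one film's rating record
#'
#' SAM dimensions (arousal, valence, liking, familiarity, dominance) and the
#' four DES intensities are drawn as rounded Gaussians clipped to the 1-9
#' scale. The film's target DES score uses the condition's target
#' distribution; non-target DES scores share the weak `nontarget`
#' distribution (clipped to 1-8 when hit-forcing is on). With
#' `force_hit = TRUE` the target score is raised, if needed, to one point
#' above the highest non-target score, emulating a 100% hit rate.
#'
#' @param config A `synth_config`.
#' @param condition Film condition.
#' @return One-row data.frame with the nine rating columns.
#' @export
generate_ratings <- function(config, condition) {
  rp <- config$rating_params[[condition]]
  if (is.null(rp)) stop("no rating parameters for condition ", condition)
  draw <- function(ms, lo = 1, hi = 9) {
    min(hi, max(lo, round(stats::rnorm(1, ms[1], ms[2]))))
  }
  sam <- vapply(c("arousal", "valence", "liking", "familiarity", "dominance"),
                function(d) draw(rp[[d]]), 0)
  conds <- emotion_conditions()
  nt_hi <- if (config$force_hit) 8 else 9
  des <- vapply(conds, function(cc) {
    if (cc == condition) draw(rp$target)
    else draw(config$rating_params$nontarget, hi = nt_hi)
  }, 0)
  if (config$force_hit) {
    top_nt <- max(des[conds != condition])
    des[condition] <- min(9, max(des[condition], top_nt + 1))
  }
  out <- as.data.frame(as.list(c(sam, stats::setNames(des, paste0("des_", conds)))))
  out
}

#' Per-subject seeds for a cohort
#'
#' Derives one RNG seed per subject from the cohort seed, allowing subjects
#' to be generated independently (e.g. streamed one at a time) while keeping
#' the whole cohort deterministic.
#'
#' @param config A `synth_config`.
#' @return Integer vector of length `n_subjects`.
#' @export
subject_seeds <- function(config) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 1L, config$n_subjects)
}

#' Generate one subject of the synthetic cohort
#'
#' Draws the subject's per-band log-normal amplitude factor, then for each of
#' the four film conditions one eyes-open baseline recording (no condition
#' effect) followed by one film recording whose per-channel band amplitudes
#' are `base_amplitude * subject factor * planted effect multiplier`, plus a
#' rating record per film.
#'
#' @param config A `synth_config`.
#' @param subject_id Integer subject index.
#' @param seed Seed for this subject, normally `subject_seeds(config)[s]`.
#' @return List with `recordings` (8 `raw_recording`s: baseline + film per
#'   condition) and `ratings` (4-row data.frame).
#' @export
generate_subject <- function(config, subject_id, seed) {
  set.seed(seed)
  lay <- config$layout
  band_names <- names(config$bands)
  conds <- emotion_conditions()
  sfac <- exp(stats::rnorm(length(band_names), 0, config$subject_sd))
  base <- outer(rep(1, length(lay$names)),
                config$base_amplitude[band_names] * sfac)
  rownames(base) <- lay$names; colnames(base) <- band_names
  recordings <- vector("list", 2L * length(conds))
  ratings <- vector("list", length(conds))
  k <- 0L
  for (cond in conds) {
    amp <- base
    for (b in band_names) {
      for (e in lay$names) {
        m <- effect_multiplier(config, cond, e, b)
        if (m != 1) amp[e, b] <- amp[e, b] * m
      }
    }
    k <- k + 1L
    recordings[[k]] <- synthesize_recording(
      list(subject_id = subject_id, amplitude = base), cond,
      "baseline_eyes_open", config$baseline_duration_s, config$fs,
      config$bands, lay, config$noise_floor)
    k <- k + 1L
    recordings[[k]] <- synthesize_recording(
      list(subject_id = subject_id, amplitude = amp), cond, "film",
      config$film_duration_s, config$fs, config$bands, lay,
      config$noise_floor)
    ratings[[match(cond, conds)]] <-
      cbind(data.frame(subject = subject_id, condition = cond),
            generate_ratings(config, cond))
  }
  list(recordings = recordings, ratings = do.call(rbind, ratings))
}

#' Generate a synthetic film-viewing EEG cohort
#'
#' Runs [generate_subject()] for every subject under per-subject seeds
#' derived from `config$seed`; deterministic (bit-identical) given the seed.
#'
#' @param config A `synth_config`.
#' @return List with `recordings` (list of `raw_recording`, 8 per subject:
#'   baseline+film per condition) and `ratings` (data.frame, one row per
#'   subject x film).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  seeds <- subject_seeds(config)
  per <- lapply(seq_len(config$n_subjects), function(s) {
    generate_subject(config, s, seeds[s])
  })
  list(recordings = do.call(c, lapply(per, `[[`, "recordings")),
       ratings = do.call(rbind, lapply(per, `[[`, "ratings")))
}

#' Write a cohort to a manifest directory
#'
#' One little-endian float64 binary file per segment plus a JSON manifest
#' (layout, sampling rate, segment table) and a ratings CSV.
#'
#' @param cohort As returned by [generate_cohort()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  segs <- lapply(seq_along(cohort$recordings), function(i) {
    rec <- cohort$recordings[[i]]
    fn <- sprintf("seg_%04d.bin", i)
    con <- file(file.path(dir, fn), "wb")
    writeBin(as.numeric(t(rec$samples)), con, size = 8, endian = "little")
    close(con)
    list(file = fn, subject_id = rec$subject_id,
         segment_kind = rec$segment_kind, condition = rec$condition,
         n_channels = nrow(rec$samples), n_samples = ncol(rec$samples),
         fs = rec$fs)
  })
  lay <- cohort$recordings[[1]]$layout
  manifest <- list(
    format = "eegemotion-cohort-v1",
    layout = lay[c("names", "scalp_set", "midline_set", "reference_set",
                   "eog_set")],
    pairs = lay$pairs,
    segments = segs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(cohort$ratings, file.path(dir, "ratings.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Manifest directory.
#' @return List with `recordings` and `ratings`.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  lay <- channel_layout(
    names = manifest$layout$names,
    scalp_set = manifest$layout$scalp_set,
    midline_set = manifest$layout$midline_set,
    pairs = if (is.matrix(manifest$pairs)) {
      lapply(seq_len(nrow(manifest$pairs)), function(i) manifest$pairs[i, ])
    } else manifest$pairs,
    reference_set = manifest$layout$reference_set %||% character(),
    eog_set = manifest$layout$eog_set %||% character())
  segs <- manifest$segments
  recordings <- lapply(seq_len(nrow(segs)), function(i) {
    con <- file(file.path(dir, segs$file[i]), "rb")
    v <- readBin(con, "numeric", n = segs$n_channels[i] * segs$n_samples[i],
                 size = 8, endian = "little")
    close(con)
    m <- matrix(v, nrow = segs$n_channels[i], byrow = TRUE)
    rownames(m) <- lay$names
    structure(
      list(subject_id = segs$subject_id[i],
           segment_kind = segs$segment_kind[i],
           condition = segs$condition[i], samples = m, fs = segs$fs[i],
           layout = lay),
      class = "raw_recording")
  })
  ratings <- utils::read.csv(file.path(dir, "ratings.csv"))
  list(recordings = recordings, ratings = ratings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
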
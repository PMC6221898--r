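#' Zero-phase band-pass filter
#'
#' Cascaded Butterworth high-pass (order 4 at `lo`) and low-pass (order 5 at
#' `hi`), each applied forward-backward (`signal::filtfilt`) for zero phase
#' distortion. The cascade keeps each section low-order and numerically
#' stable even for a 1-Hz edge at a 500-Hz rate; the effective attenuation
#' is twice each section's order.
#'
#' @param rec A `raw_recording`.
#' @param lo,hi Passband edges in Hz, `0 < lo < hi < fs/2`.
#' @return The filtered `raw_recording`.
#' @export
bandpass_filter <- function(rec, lo = 1, hi = 35) {
  fs <- rec$fs
  if (!(lo > 0 && lo < hi && hi < fs / 2)) {
    stop("invalid band: need 0 < lo < hi < fs/2")
  }
  hp <- signal::butter(4, lo / (fs / 2), type = "high")
  lp <- signal::butter(5, hi / (fs / 2), type = "low")
  out <- t(apply(rec$samples, 1, function(ch) {
    signal::filtfilt(lp, signal::filtfilt(hp, ch))
  }))
  rownames(out) <- rownames(rec$samples)
  rec$samples <- out
  rec
}

#' Re-reference to the mean of reference channels
#'
#' Subtracts the across-sample mean of the reference (mastoid) channels from
#' every scalp channel, giving a symmetric reference. When the layout has no
#' reference channels (the synthetic generator emits already-referenced
#' signals) the recording is returned unchanged with a warning.
#'
#' @param rec A `raw_recording`.
#' @param reference_labels Labels to average; defaults to the layout's
#'   `reference_set`.
#' @return The re-referenced `raw_recording`.
#' @export
rereference <- function(rec, reference_labels = rec$layout$reference_set) {
  if (length(reference_labels) == 0 ||
      !all(reference_labels %in% rownames(rec$samples))) {
    warning("no reference channels present; recording returned unchanged")
    return(rec)
  }
  ref <- colMeans(rec$samples[reference_labels, , drop = FALSE])
  rec$samples <- sweep(rec$samples, 2, ref)
  rec
}

#' Segment a recording into overlapping epochs
#'
#' Fixed-length windows at a hop of `(1 - overlap_frac) * epoch_len_s`;
#' a trailing partial window is dropped.
#'
#' @param rec A `raw_recording`.
#' @param epoch_len_s Window length in seconds (default 2).
#' @param overlap_frac Fractional overlap in `[0, 1)` (default 0.5).
#' @return An `epoch_set`: list with `subject_id`, `condition`,
#'   `segment_kind`, `epochs` (list of electrodes x samples matrices), `fs`,
#'   `layout`, `kept_fraction`.
#' @export
segment_epochs <- function(rec, epoch_len_s = 2, overlap_frac = 0.5) {
  n <- ncol(rec$samples)
  len <- round(epoch_len_s * rec$fs)
  if (len > n) stop("epoch longer than recording")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac in [0,1)")
  hop <- max(1L, round((1 - overlap_frac) * len))
  starts <- seq(1L, n - len + 1L, by = hop)
  epochs <- lapply(starts, function(s) {
    rec$samples[, s:(s + len - 1L), drop = FALSE]
  })
  structure(
    list(subject_id = rec$subject_id, condition = rec$condition,
         segment_kind = rec$segment_kind, epochs = epochs, fs = rec$fs,
         layout = rec$layout, kept_fraction = 1),
    class = "epoch_set")
}

#' Reject epochs exceeding an amplitude threshold
#'
#' Removes every epoch in which any channel sample exceeds
#' `amp_threshold_uV` in absolute value and updates `kept_fraction`.
#' The +/-100 uV default is a common scalp-EEG artifact bound; thresholds
#' vary across subjects in practice and are configurable per call.
#'
#' @param es An `epoch_set`.
#' @param amp_threshold_uV Positive rejection threshold in microvolts; may
#'   be `Inf` for a no-op.
#' @return The pruned `epoch_set`.
#' @export
reject_artifacts <- function(es, amp_threshold_uV = 100) {
  if (amp_threshold_uV <= 0) stop("threshold must be positive")
  keep <- vapply(es$epochs, function(ep) max(abs(ep)) <= amp_threshold_uV,
                 TRUE)
  if (!any(keep)) {
    stop("all epochs rejected for subject ", es$subject_id,
         ", condition ", es$condition)
  }
  es$kept_fraction <- es$kept_fraction * mean(keep)
  es$epochs <- es$epochs[keep]
  es
}

#' Band power per electrode from an epoch set
#'
#' Each epoch is Hanning-tapered and Fourier-transformed; per-bin power is
#' window-power compensated (divided by `n * sum(w^2)`, one-sided doubling)
#' so that the *sum* of bin powers recovers the signal variance (Parseval).
#' Bin powers are averaged across epochs, and the band value is the *mean*
#' over the bins with `lo <= freq < hi` (half-open, so a shared edge belongs
#' to the upper band), in microvolts squared per bin.
#'
#' @param es An `epoch_set` with at least one epoch.
#' @param bands Named list of half-open band edges.
#' @return data.frame(electrode, band, power, n_bins); `power * n_bins` is
#'   the total band power.
#' @export
band_power <- function(es, bands = default_bands()) {
  if (length(es$epochs) == 0) stop("epoch set has no epochs")
  len <- ncol(es$epochs[[1]])
  n_ch <- nrow(es$epochs[[1]])
  freqs <- seq(0, es$fs / 2, by = es$fs / len)
  nyq_i <- len %/% 2 + 1L
  for (b in names(bands)) {
    if (bands[[b]][2] > es$fs / 2) {
      stop("band ", b, " outside resolvable range")
    }
  }
  w <- 0.5 * (1 - cos(2 * pi * seq(0, len - 1) / len))  # periodic Hann
  wnorm <- len * sum(w^2)
  # stack epochs column-wise: one big matrix FFT
  big <- matrix(unlist(lapply(es$epochs, function(ep) t(ep * rep(w, each = n_ch)))),
                nrow = len)
  spec <- stats::mvfft(big)
  p <- Mod(spec[seq_len(nyq_i), , drop = FALSE])^2 / wnorm
  if (nyq_i > 2) p[2:(nyq_i - 1L), ] <- 2 * p[2:(nyq_i - 1L), ]
  if (len %% 2 == 1) p[nyq_i, ] <- 2 * p[nyq_i, ]
  # average the per-bin power across epochs, keeping channels apart
  p_arr <- array(p, dim = c(nyq_i, n_ch, length(es$epochs)))
  p_mean <- rowMeans(p_arr, dims = 2)                # bins x channels
  out <- do.call(rbind, lapply(names(bands), function(b) {
    idx <- which(freqs[seq_len(nyq_i)] >= bands[[b]][1] &
                   freqs[seq_len(nyq_i)] < bands[[b]][2])
    data.frame(electrode = es$layout$names,
               band = b,
               power = colMeans(p_mean[idx, , drop = FALSE]),
               n_bins = length(idx))
  }))
  rownames(out) <- NULL
  out
}

#' Band powers for a whole cohort
#'
#' Runs filter -> (re-reference) -> segment -> artifact-reject -> band power
#' over every recording, returning one long table. Film rows carry the film
#' condition; baseline rows keep `segment_kind = "baseline_eyes_open"` with
#' the condition of the film they precede.
#'
#' @param recordings List of `raw_recording`.
#' @param bands Band definition list.
#' @param filter_band `c(lo, hi)` pass band in Hz, or `NULL` to skip.
#' @param epoch_len_s,overlap_frac Epoching parameters (2 s, 50%).
#' @param amp_threshold_uV Artifact threshold (microvolts).
#' @return data.frame(subject, condition, segment_kind, electrode, band,
#'   power, n_bins, kept_fraction).
#' @export
compute_band_powers <- function(recordings, bands = default_bands(),
                                filter_band = c(1, 35),
                                epoch_len_s = 2, overlap_frac = 0.5,
                                amp_threshold_uV = 100) {
  rows <- lapply(recordings, function(rec) {
    if (!is.null(filter_band)) {
      rec <- bandpass_filter(rec, filter_band[1], filter_band[2])
    }
    if (length(rec$layout$reference_set) > 0) rec <- rereference(rec)
    es <- segment_epochs(rec, epoch_len_s, overlap_frac)
    es <- reject_artifacts(es, amp_threshold_uV)
    bp <- band_power(es, bands)
    cbind(data.frame(subject = rec$subject_id, condition = rec$condition,
                     segment_kind = rec$segment_kind), bp,
          kept_fraction = es$kept_fraction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline-normalize condition band powers
#'
#' For each subject, condition and band, divides the film-segment power at
#' every electrode by the scalar mean baseline power of that band across the
#' `N = |scalp_set|` scalp electrodes, taken from the eyes-open baseline
#' preceding that film. The denominator is a per-subject, per-condition,
#' per-band scalar, so the scalp topography is preserved.
#'
#' @param powers Long table from [compute_band_powers()] (film rows), or a
#'   data.frame(subject, condition, electrode, band, power).
#' @param baseline_powers Baseline rows in the same format (matched on
#'   subject, condition, band). If `powers` contains both segment kinds and
#'   `baseline_powers` is `NULL`, the split is done internally.
#' @param scalp_set Electrodes entering the baseline average.
#' @return A `band_power_table`: data.frame(subject, condition, electrode,
#'   band, absolute, normalized) with attribute `n_norm = |scalp_set|`.
#' @export
baseline_normalize <- function(powers, baseline_powers = NULL,
                               scalp_set = default_layout()$scalp_set) {
  if (length(scalp_set) == 0) stop("scalp_set must be non-empty")
  if (is.null(baseline_powers)) {
    if (!"segment_kind" %in% names(powers)) {
      stop("need baseline_powers or a segment_kind column")
    }
    baseline_powers <- powers[powers$segment_kind != "film", , drop = FALSE]
    powers <- powers[powers$segment_kind == "film", , drop = FALSE]
  }
  bl <- baseline_powers[baseline_powers$electrode %in% scalp_set, ,
                        drop = FALSE]
  den <- stats::aggregate(power ~ subject + condition + band, data = bl,
                          FUN = mean)
  names(den)[names(den) == "power"] <- "baseline_mean"
  out <- merge(powers[, c("subject", "condition", "electrode", "band",
                          "power")],
               den, by = c("subject", "condition", "band"), sort = FALSE)
  if (nrow(out) < nrow(powers)) {
    stop("missing baseline for some subject/condition/band combinations")
  }
  if (any(out$baseline_mean <= 0)) {
    stop("zero or negative baseline denominator")
  }
  out$normalized <- out$power / out$baseline_mean
  names(out)[names(out) == "power"] <- "absolute"
  out <- out[order(out$subject, out$condition, out$band, out$electrode),
             c("subject", "condition", "electrode", "band", "absolute",
               "normalized")]
  rownames(out) <- NULL
  attr(out, "n_norm") <- length(scalp_set)
  class(out) <- c("band_power_table", "data.frame")
  out
}
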
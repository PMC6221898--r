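#' Frontal asymmetry for an electrode pair
#'
#' Right-hemisphere minus left-hemisphere normalized band power, per subject
#' and condition (e.g. F3/F4 theta asymmetry = theta at F4 minus theta at
#' F3). Dimensionless because the inputs are baseline-normalized.
#'
#' @param table A `band_power_table` from [baseline_normalize()].
#' @param pair `c(left, right)` electrode labels.
#' @param band Band name.
#' @param value Column to difference: `"normalized"` (default) or
#'   `"absolute"`.
#' @return data.frame(subject, condition, asymmetry).
#' @export
asymmetry <- function(table, pair = c("F3", "F4"), band = "alpha",
                      value = "normalized") {
  stopifnot(length(pair) == 2)
  sub <- table[table$band == band & table$electrode %in% pair, , drop = FALSE]
  have <- unique(sub$electrode)
  if (!all(pair %in% have)) {
    stop("electrode(s) missing: ", paste(setdiff(pair, have), collapse = ", "))
  }
  lhs <- sub[sub$electrode == pair[1], c("subject", "condition", value)]
  rhs <- sub[sub$electrode == pair[2], c("subject", "condition", value)]
  m <- merge(rhs, lhs, by = c("subject", "condition"),
             suffixes = c("_r", "_l"), sort = TRUE)
  data.frame(subject = m$subject, condition = m$condition,
             asymmetry = m[[paste0(value, "_r")]] - m[[paste0(value, "_l")]])
}

#' Composite frontal averages
#'
#' `F_left = (FP1 + F3)/2` and `F_right = (FP2 + F4)/2` per band, subject
#' and condition.
#'
#' @param table A `band_power_table`.
#' @param value `"normalized"` (default) or `"absolute"`.
#' @return data.frame(subject, condition, band, F_left, F_right).
#' @export
composite_frontal <- function(table, value = "normalized") {
  need <- c("FP1", "FP2", "F3", "F4")
  sub <- table[table$electrode %in% need, , drop = FALSE]
  if (!all(need %in% unique(sub$electrode))) {
    stop("electrode(s) missing: ",
         paste(setdiff(need, unique(sub$electrode)), collapse = ", "))
  }
  wide <- stats::reshape(
    sub[, c("subject", "condition", "band", "electrode", value)],
    idvar = c("subject", "condition", "band"), timevar = "electrode",
    direction = "wide")
  cn <- function(e) paste0(value, ".", e)
  out <- data.frame(subject = wide$subject, condition = wide$condition,
                    band = wide$band,
                    F_left = (wide[[cn("FP1")]] + wide[[cn("F3")]]) / 2,
                    F_right = (wide[[cn("FP2")]] + wide[[cn("F4")]]) / 2)
  out[order(out$subject, out$condition, out$band), ]
}

#' Feature-set identifiers
#' @return Character vector of the five classification feature sets.
#' @export
feature_set_ids <- function() {
  c("original75", "plus_midline", "plus_asym", "plus_all19", "new19")
}

# the 4 asymmetry features added to the whole-scalp set
asym_feature_spec <- function() {
  list(asym_theta_FP1FP2 = list(pair = c("FP1", "FP2"), band = "theta"),
       asym_alpha_FP1FP2 = list(pair = c("FP1", "FP2"), band = "alpha"),
       asym_theta_F3F4   = list(pair = c("F3", "F4"), band = "theta"),
       asym_alpha_F3F4   = list(pair = c("F3", "F4"), band = "alpha"))
}

#' Assemble a named feature set
#'
#' Builds one row per subject x condition with the columns of the requested
#' set: `original75` = theta/alpha/beta power at the 25 non-midline
#' electrodes; `plus_midline` adds the 15 midline powers (3 bands x FZ, FCZ,
#' CZ, CPZ, PZ); `plus_asym` adds the 4 frontal asymmetries (FP1/FP2 and
#' F3/F4, theta and alpha); `plus_all19` adds all 19; `new19` is the 19 new
#' features alone. Column counts are 75 / 90 / 79 / 94 / 19.
#'
#' @param table A `band_power_table`.
#' @param set_id One of [feature_set_ids()].
#' @param layout A `channel_layout`.
#' @param value Power column used for electrode features, `"normalized"`
#'   (default) or `"absolute"`.
#' @return A `feature_table` data.frame: subject, condition, then feature
#'   columns; attribute `set_id`.
#' @export
assemble_feature_set <- function(table, set_id = "plus_all19",
                                 layout = default_layout(),
                                 value = "normalized") {
  set_id <- match.arg(set_id, feature_set_ids())
  bands <- unique(table$band)
  scalp25 <- scalp_feature_electrodes(layout)
  midline <- layout$midline_set

  # assemble by hand for a stable column order: band-major, electrode-minor
  ids <- unique(table[, c("subject", "condition")])
  ids <- ids[order(ids$subject, ids$condition), ]
  lookup <- function(electrode, band) {
    sub <- table[table$electrode == electrode & table$band == band, ,
                 drop = FALSE]
    if (nrow(sub) == 0) stop("electrode missing: ", electrode)
    sub <- sub[order(sub$subject, sub$condition), ]
    if (nrow(sub) != nrow(ids)) stop("incomplete table at ", electrode)
    sub[[value]]
  }
  cols <- list()
  add_power_block <- function(cols, electrodes) {
    for (b in bands) for (e in electrodes) {
      cols[[paste0(b, "_", e)]] <- lookup(e, b)
    }
    cols
  }
  if (set_id %in% c("original75", "plus_midline", "plus_asym",
                    "plus_all19")) {
    cols <- add_power_block(cols, scalp25)
  }
  if (set_id %in% c("plus_midline", "plus_all19", "new19")) {
    cols <- add_power_block(cols, midline)
  }
  if (set_id %in% c("plus_asym", "plus_all19", "new19")) {
    for (nm in names(asym_feature_spec())) {
      sp <- asym_feature_spec()[[nm]]
      a <- asymmetry(table, sp$pair, sp$band, value)
      a <- a[order(a$subject, a$condition), ]
      cols[[nm]] <- a$asymmetry
    }
  }
  out <- cbind(ids, as.data.frame(cols))
  rownames(out) <- NULL
  if (anyNA(out)) stop("feature table contains missing values")
  attr(out, "set_id") <- set_id
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Hit rate of a film's target emotion
#'
#' Fraction of subjects whose DES score for the film's target emotion is at
#' least one point higher than every non-target DES score.
#'
#' @param ratings Ratings table with `condition` and `des_*` columns.
#' @param film Film condition whose hit rate is wanted.
#' @return Fraction in `[0, 1]`.
#' @export
hit_rate <- function(ratings, film) {
  des_cols <- paste0("des_", emotion_conditions())
  if (!all(des_cols %in% names(ratings))) stop("DES columns missing")
  sub <- ratings[ratings$condition == film, , drop = FALSE]
  if (nrow(sub) == 0) stop("no ratings for film ", film)
  target <- sub[[paste0("des_", film)]]
  others <- as.matrix(sub[, setdiff(des_cols, paste0("des_", film))])
  mean(target >= apply(others, 1, max) + 1)
}
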
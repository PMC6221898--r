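#' Channel layout for a multichannel EEG montage
#'
#' Describes the electrode montage used throughout the pipeline: the full
#' ordered label set, the scalp subset entering the baseline-normalization
#' average, the sagittal midline subset, the homologous left/right frontal
#' pairs used for asymmetry features, and optional reference (mastoid) and
#' EOG labels.
#'
#' @param names Ordered character vector of all electrode labels.
#' @param scalp_set Labels entering the across-electrode baseline average
#'   (excludes reference and EOG channels).
#' @param midline_set Sagittal midline labels (default `FZ, FCZ, CZ, CPZ, PZ`).
#' @param pairs List of length-2 character vectors, each `c(left, right)`.
#' @param reference_set Mastoid labels, possibly empty.
#' @param eog_set EOG labels, possibly empty.
#'
#' @return An object of class `channel_layout`.
#' @examples
#' lay <- default_layout()
#' length(lay$scalp_set)
#' @export
channel_layout <- function(names,
                           scalp_set = names,
                           midline_set = c("FZ", "FCZ", "CZ", "CPZ", "PZ"),
                           pairs = list(c("FP1", "FP2"), c("F3", "F4")),
                           reference_set = character(),
                           eog_set = character()) {
  names <- as.character(names)
  if (length(names) == 0L) stop("layout must contain at least one electrode")
  if (anyDuplicated(names)) stop("duplicate electrode labels in layout")
  pair_members <- unlist(pairs)
  missing <- setdiff(c(scalp_set, midline_set, pair_members,
                       reference_set, eog_set), names)
  if (length(missing) > 0L) {
    stop("labels not present in layout: ", paste(missing, collapse = ", "))
  }
  if (length(intersect(midline_set, pair_members)) > 0L) {
    stop("midline_set and asymmetry pair members must be disjoint")
  }
  if (length(intersect(scalp_set, c(reference_set, eog_set))) > 0L) {
    stop("scalp_set must exclude reference and EOG labels")
  }
  for (p in pairs) {
    if (length(p) != 2L) stop("each pair must have exactly two labels")
  }
  structure(
    list(names = names, scalp_set = as.character(scalp_set),
         midline_set = as.character(midline_set), pairs = pairs,
         reference_set = as.character(reference_set),
         eog_set = as.character(eog_set)),
    class = "channel_layout")
}

#' Default 31-channel 10/20 montage
#'
#' The 31 scalp sites of an extended 10/20 cap (FPZ through O2), all of which
#' enter the baseline-normalization average; midline `FZ, FCZ, CZ, CPZ, PZ`;
#' asymmetry pairs `FP1/FP2` and `F3/F4`. Mastoid and EOG channels are not
#' included: the synthetic generator emits already-referenced scalp signals.
#'
#' @return A `channel_layout` with 31 electrodes.
#' @export
default_layout <- function() {
  scalp <- c("FPZ", "FP1", "FP2", "F7", "F3", "FZ", "F4", "F8",
             "FT7", "FC3", "FCZ", "FC4", "FT8", "T3", "C3", "CZ",
             "C4", "T4", "TP7", "CP3", "CPZ", "CP4", "TP8", "T5",
             "P3", "PZ", "P4", "T6", "O1", "OZ", "O2")
  channel_layout(names = scalp, scalp_set = scalp)
}

#' Electrodes of the whole-scalp feature set
#'
#' The 25 non-midline electrodes whose three band powers form the 75-feature
#' whole-scalp set: the montage minus the five midline sites and minus FPZ.
#'
#' @param layout A `channel_layout`.
#' @return Character vector of 25 labels (for the default layout).
#' @export
scalp_feature_electrodes <- function(layout = default_layout()) {
  setdiff(layout$scalp_set, c(layout$midline_set, "FPZ"))
}

#' @export
print.channel_layout <- function(x, ...) {
  cat("<channel_layout> ", length(x$names), " electrodes\n", sep = "")
  cat("  scalp set (N = ", length(x$scalp_set), ")\n", sep = "")
  cat("  midline: ", paste(x$midline_set, collapse = " "), "\n", sep = "")
  cat("  pairs: ",
      paste(vapply(x$pairs, paste, "", collapse = "/"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
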
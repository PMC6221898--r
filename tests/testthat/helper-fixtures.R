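# Shared fixtures: tiny layouts, hand-built band-power tables, and a cached
# reduced-scale cohort so several test files can reuse one simulation.

tiny_layout <- function() {
  channel_layout(
    names = c("FP1", "FP2", "F3", "F4", "FZ", "FCZ", "CZ", "CPZ", "PZ"),
    midline_set = c("FZ", "FCZ", "CZ", "CPZ", "PZ"),
    pairs = list(c("FP1", "FP2"), c("F3", "F4")))
}

one_channel_layout <- function(label = "CZ") {
  channel_layout(names = label, scalp_set = label, midline_set = label,
                 pairs = list())
}

# band-power table built directly from normalized values:
# `values` is a data.frame(subject, condition, electrode, band, normalized)
manual_bpt <- function(values) {
  values$absolute <- values$normalized
  values <- values[, c("subject", "condition", "electrode", "band",
                       "absolute", "normalized")]
  attr(values, "n_norm") <- length(unique(values$electrode))
  class(values) <- c("band_power_table", "data.frame")
  values
}

# full-montage normalized table for `n` subjects x 4 conditions from a
# generator function value_fn(subject, condition, electrode, band)
synth_bpt <- function(n, value_fn, layout = default_layout(),
                      bands = names(default_bands())) {
  grid <- expand.grid(subject = seq_len(n),
                      condition = emotion_conditions(),
                      electrode = layout$names, band = bands,
                      stringsAsFactors = FALSE)
  grid$normalized <- mapply(value_fn, grid$subject, grid$condition,
                            grid$electrode, grid$band)
  manual_bpt(grid)
}

# reduced-scale planted-effect cohort, computed once per test run
cached_cohort_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- synth_config(n_subjects = 10, fs = 128, film_duration_s = 20,
                         baseline_duration_s = 10, seed = 42)
      cohort <- generate_cohort(sc)
      powers <- compute_band_powers(cohort$recordings,
                                    filter_band = NULL)
      cache <<- list(
        config = sc, ratings = cohort$ratings,
        table = baseline_normalize(powers,
                                   scalp_set = sc$layout$scalp_set))
    }
    cache
  }
})
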
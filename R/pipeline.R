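#' Full statistical battery over a cohort's features and ratings
#'
#' Reproduces the analysis structure of the film-viewing paradigm:
#' per-film hit rates; 2x2 (emotion x hemisphere) within-subject interaction
#' tests — multivariate across theta+alpha and univariate per band — for the
#' positive pair (amusement vs tenderness) and the negative pair (anger vs
#' fear) at FP1/FP2, F3/F4 and the composite F_left/F_right sites; paired t
#' tests per band at the five midline sites for both pairs; stepwise
#' regressions predicting each film's target rating from the 19
#' asymmetry+midline features; and partial correlations of liking and
#' dominance with those features (controlling arousal, valence and
#' familiarity) within each pair, BH-FDR corrected per family.
#'
#' @param table A `band_power_table`.
#' @param ratings Ratings data.frame (subject, condition, SAM + DES columns).
#' @param layout A `channel_layout`.
#' @return List of data.frames: `hit_rates`, `interactions`, `midline_t`,
#'   `regressions`, `partial_correlations`.
#' @export
stats_report <- function(table, ratings, layout = default_layout()) {
  conds_all <- emotion_conditions()
  pairs_task <- list(positive = c("amusement", "tenderness"),
                     negative = c("anger", "fear"))
  present <- intersect(conds_all, unique(table$condition))

  hit_rates <- do.call(rbind, lapply(intersect(conds_all,
                                               unique(ratings$condition)),
                                     function(f) {
    data.frame(film = f, hit_rate = hit_rate(ratings, f))
  }))

  # per-site electrode getter: composite sites average FP1+F3 / FP2+F4
  site_values <- function(site, band, cond) {
    sub <- table[table$band == band & table$condition == cond, , drop = FALSE]
    sub <- sub[order(sub$subject), ]
    get <- function(e) sub$normalized[sub$electrode == e]
    switch(site,
           "FP1/FP2" = cbind(left = get("FP1"), right = get("FP2")),
           "F3/F4" = cbind(left = get("F3"), right = get("F4")),
           "Fl/Fr" = cbind(left = (get("FP1") + get("F3")) / 2,
                           right = (get("FP2") + get("F4")) / 2))
  }
  inter_rows <- list()
  for (pw in names(pairs_task)) {
    pr <- pairs_task[[pw]]
    if (!all(pr %in% present)) next
    for (site in c("FP1/FP2", "F3/F4", "Fl/Fr")) {
      vals <- lapply(c("theta", "alpha"), function(b) {
        v1 <- site_values(site, b, pr[1])
        v2 <- site_values(site, b, pr[2])
        array(c(v1[, "left"], v1[, "right"], v2[, "left"], v2[, "right"]),
              c(nrow(v1), 2, 2))  # subjects x hemisphere x condition
      })
      n <- dim(vals[[1]])[1]
      dvs <- array(NA_real_, c(n, 2, 2, 2))
      # reorder to subjects x condition x hemisphere x band
      for (j in 1:2) dvs[, , , j] <- aperm(vals[[j]], c(1, 3, 2))
      mv <- within_interaction_multivariate(
        dvs, label = paste(pw, site, "theta+alpha"))
      inter_rows[[length(inter_rows) + 1L]] <- data.frame(
        pair = pw, site = site, band = "theta+alpha", test = "multivariate",
        statistic = mv$statistic, df1 = mv$df[1], df2 = mv$df[2],
        p = mv$p, effect_size = mv$effect_size, lambda = mv$lambda)
      for (j in 1:2) {
        b <- c("theta", "alpha")[j]
        uv <- within_interaction_univariate(dvs[, , , j],
                                            label = paste(pw, site, b))
        inter_rows[[length(inter_rows) + 1L]] <- data.frame(
          pair = pw, site = site, band = b, test = "univariate",
          statistic = uv$statistic, df1 = uv$df[1], df2 = uv$df[2],
          p = uv$p, effect_size = uv$effect_size, lambda = NA_real_)
      }
    }
  }
  interactions <- if (length(inter_rows)) do.call(rbind, inter_rows) else NULL

  midline_rows <- list()
  for (pw in names(pairs_task)) {
    pr <- pairs_task[[pw]]
    if (!all(pr %in% present)) next
    for (b in names(default_bands())) {
      for (e in layout$midline_set) {
        sub <- table[table$band == b & table$electrode == e, , drop = FALSE]
        x <- sub$normalized[sub$condition == pr[1]][order(
          sub$subject[sub$condition == pr[1]])]
        y <- sub$normalized[sub$condition == pr[2]][order(
          sub$subject[sub$condition == pr[2]])]
        tt <- paired_t(x, y, label = paste(pw, b, e))
        midline_rows[[length(midline_rows) + 1L]] <- data.frame(
          pair = pw, band = b, electrode = e, mean_diff = tt$mean_diff,
          sd_diff = tt$sd_diff, t = tt$statistic, df = tt$df, p = tt$p,
          d_z = tt$d_z, d_av = tt$d_av)
      }
    }
  }
  midline_t <- if (length(midline_rows)) do.call(rbind, midline_rows) else NULL

  # 19-feature predictor block for regression / partial correlation
  ft19 <- assemble_feature_set(table, "new19", layout)
  feat_cols <- setdiff(names(ft19), c("subject", "condition"))
  merged <- merge(ft19, ratings, by = c("subject", "condition"))
  merged <- merged[order(merged$subject, merged$condition), ]

  reg_rows <- list()
  for (cond in intersect(conds_all, unique(merged$condition))) {
    yv <- merged[[paste0("des_", cond)]]
    fit <- stepwise_regression(as.matrix(merged[, feat_cols]), yv)
    cf <- data.frame(outcome = cond, fit$coefficients,
                     adj_r_squared = fit$adj_r_squared,
                     model_F = fit$F, model_p = fit$p_value,
                     row.names = NULL)
    reg_rows[[length(reg_rows) + 1L]] <- cf
  }
  regressions <- if (length(reg_rows)) do.call(rbind, reg_rows) else NULL

  pc_rows <- list()
  for (pw in names(pairs_task)) {
    pr <- pairs_task[[pw]]
    sub <- merged[merged$condition %in% pr, , drop = FALSE]
    if (nrow(sub) == 0 || length(unique(sub$condition)) < 2) next
    covs <- as.matrix(sub[, c("arousal", "valence", "familiarity")])
    for (rating in c("liking", "dominance")) {
      res <- lapply(feat_cols, function(fc) {
        pc <- suppressWarnings(
          partial_correlation(sub[[fc]], sub[[rating]], covs))
        data.frame(pair = pw, rating = rating, feature = fc,
                   r = pc$statistic, df = pc$df, p = pc$p)
      })
      fam <- do.call(rbind, res)
      # a constant rating column at small n yields undefined correlations;
      # such rows are excluded from the BH family
      fam <- fam[is.finite(fam$p), , drop = FALSE]
      if (nrow(fam) > 0) {
        fam$p_adj <- bh_fdr(fam$p)
        pc_rows[[length(pc_rows) + 1L]] <- fam
      }
    }
  }
  partial_correlations <- if (length(pc_rows)) do.call(rbind, pc_rows) else NULL

  list(hit_rates = hit_rates, interactions = interactions,
       midline_t = midline_t, regressions = regressions,
       partial_correlations = partial_correlations)
}

#' Pipeline run configuration
#'
#' Bundles the synthetic-cohort configuration with the preprocessing,
#' feature, statistics and classification parameters of a full run. All
#' defaults mirror the analysis chain's standard parameters: 1-35 Hz pass
#' band, 2-s Hanning windows with 50% overlap, +/-100 uV artifact
#' threshold, the five feature sets, the three classification tasks, and a
#' linear-kernel SVM with cost 1.
#'
#' @param synth A `synth_config`.
#' @param filter_band `c(lo, hi)` in Hz.
#' @param epoch_len_s,overlap_frac Epoching parameters.
#' @param amp_threshold_uV Artifact rejection threshold.
#' @param set_ids Feature sets to assemble and classify.
#' @param tasks Classification tasks.
#' @param classifier_params,top_k,slda_params See [loso_cv()].
#' @param seed Seed for the whole run (overrides `synth$seed`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(synth = synth_config(),
                       filter_band = c(1, 35),
                       epoch_len_s = 2, overlap_frac = 0.5,
                       amp_threshold_uV = 100,
                       set_ids = feature_set_ids(),
                       tasks = c("tender_vs_amuse", "anger_vs_fear",
                                 "four_class"),
                       classifier_params = list(kernel = "linear", cost = 1),
                       top_k = NULL, slda_params = list(),
                       seed = synth$seed) {
  synth$seed <- as.integer(seed)
  structure(
    list(synth = synth, filter_band = filter_band,
         epoch_len_s = epoch_len_s, overlap_frac = overlap_frac,
         amp_threshold_uV = amp_threshold_uV, set_ids = set_ids,
         tasks = tasks, classifier_params = classifier_params,
         top_k = top_k, slda_params = slda_params,
         seed = as.integer(seed)),
    class = "run_config")
}

#' Run the full pipeline: simulate, preprocess, features, stats, classify
#'
#' Streams the synthetic cohort one subject at a time (raw signals are
#' discarded once their band powers are computed), then baseline-normalizes,
#' assembles the feature sets, runs the statistical battery, and runs the
#' LOSO classification experiment. Writes CSV/JSON outputs plus a manifest
#' (config hash, package version) into `out_dir`. Deterministic given the
#' seed: two runs with the same config produce identical report files.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory, created if needed.
#' @param write_signals Also dump raw recordings as a cohort manifest
#'   directory under `out_dir/cohort` (large; default FALSE).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `band_powers`, `features`, `stats`,
#'   `classification`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, write_signals = FALSE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  sc <- config$synth
  seeds <- subject_seeds(sc)

  say("simulate + preprocess: ", sc$n_subjects, " subjects")
  bp_rows <- vector("list", sc$n_subjects)
  rat_rows <- vector("list", sc$n_subjects)
  for (s in seq_len(sc$n_subjects)) {
    subj <- generate_subject(sc, s, seeds[s])
    bp <- tryCatch(
      compute_band_powers(subj$recordings, sc$bands, config$filter_band,
                          config$epoch_len_s, config$overlap_frac,
                          config$amp_threshold_uV),
      error = function(e) stop("stage preprocess, subject ", s, ": ",
                               conditionMessage(e)))
    if (write_signals) {
      write_cohort(list(recordings = subj$recordings,
                        ratings = subj$ratings),
                   file.path(out_dir, "cohort", sprintf("subject_%02d", s)))
    }
    bp_rows[[s]] <- bp
    rat_rows[[s]] <- subj$ratings
  }
  powers <- do.call(rbind, bp_rows)
  ratings <- do.call(rbind, rat_rows)
  table <- baseline_normalize(powers, scalp_set = sc$layout$scalp_set)
  utils::write.csv(table, file.path(out_dir, "band_powers.csv"),
                   row.names = FALSE)
  utils::write.csv(ratings, file.path(out_dir, "ratings.csv"),
                   row.names = FALSE)

  say("features: ", length(config$set_ids), " sets")
  features <- list()
  for (sid in config$set_ids) {
    ft <- tryCatch(assemble_feature_set(table, sid, sc$layout),
                   error = function(e) stop("stage features (", sid, "): ",
                                            conditionMessage(e)))
    features[[sid]] <- ft
    utils::write.csv(ft, file.path(out_dir,
                                   paste0("features_", sid, ".csv")),
                     row.names = FALSE)
  }

  say("stats battery")
  stats_out <- tryCatch(stats_report(table, ratings, sc$layout),
                        error = function(e) stop("stage stats: ",
                                                 conditionMessage(e)))
  jsonlite::write_json(stats_out, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  say("classification: ", length(config$tasks), " tasks x ",
      length(config$set_ids), " sets")
  cls <- tryCatch(
    run_feature_set_experiment(table, config$set_ids, config$tasks,
                               sc$layout, config$classifier_params,
                               config$top_k, config$slda_params),
    error = function(e) stop("stage classify: ", conditionMessage(e)))
  utils::write.csv(cls$summary, file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  all_preds <- do.call(rbind, lapply(names(cls$reports), function(sid) {
    do.call(rbind, lapply(names(cls$reports[[sid]]), function(task) {
      cbind(data.frame(set_id = sid, task = task),
            cls$reports[[sid]][[task]]$predictions)
    }))
  }))
  utils::write.csv(all_preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config_to_list(config), cfg_path,
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "eegemotion",
    version = as.character(utils::packageVersion("eegemotion")),
    config_hash = unname(tools::md5sum(cfg_path)),
    n_subjects = sc$n_subjects, seed = config$seed,
    n_norm = attr(table, "n_norm"),
    power_scope = "artifact-free epochs averaged",
    files = c("band_powers.csv", "ratings.csv",
              paste0("features_", config$set_ids, ".csv"),
              "stats_report.json", "classification.csv",
              "predictions.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(band_powers = table, ratings = ratings,
                 features = features, stats = stats_out,
                 classification = cls, out_dir = out_dir))
}

# JSON-serializable view of a run_config (functions/classes flattened)
config_to_list <- function(config) {
  sc <- config$synth
  list(
    synth = list(
      n_subjects = sc$n_subjects, fs = sc$fs,
      film_duration_s = sc$film_duration_s,
      baseline_duration_s = sc$baseline_duration_s,
      bands = sc$bands, base_amplitude = as.list(sc$base_amplitude),
      effects = sc$effects, subject_sd = sc$subject_sd,
      noise_floor = sc$noise_floor, force_hit = sc$force_hit,
      layout = sc$layout[c("names", "scalp_set", "midline_set")],
      seed = sc$seed),
    filter_band = config$filter_band, epoch_len_s = config$epoch_len_s,
    overlap_frac = config$overlap_frac,
    amp_threshold_uV = config$amp_threshold_uV,
    set_ids = config$set_ids, tasks = config$tasks,
    classifier_params = config$classifier_params,
    top_k = config$top_k, slda_params = config$slda_params,
    seed = config$seed)
}
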
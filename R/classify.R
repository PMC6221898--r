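#' Sparse linear discriminant feature ranking
#'
#' Sparse LDA by elastic-net-penalized optimal scoring: for each of the
#' `K - 1` discriminant directions, alternate between (a) solving the
#' penalized regression of the scored class indicators on the standardized
#' features (elastic net; L1 weight `sparsity`, ridge weight `ridge`) and
#' (b) updating the class scores by the D-orthogonal projection of
#' `D^-1 Y' X beta`, where `D` holds the class proportions. The sparseness
#' constraint zeroes many coefficients; surviving features are ranked by
#' the maximum absolute coefficient across directions (ties broken by
#' column order). Features are standardized internally, so the ranking is
#' invariant to feature scaling. The procedure is deterministic.
#'
#' @param X Numeric matrix/data.frame, instances x features.
#' @param y Class labels, `>= 2` classes with `>= 2` instances each.
#' @param sparsity L1 penalty weight (glmnet scale), default 1e-3.
#' @param ridge Ridge penalty weight, default 1e-2.
#' @param max_iter,tol Optimal-scoring iteration controls.
#' @return An `slda_model`: list with `vectors` (features x K-1 coefficient
#'   matrix, standardized scale), `ranking` (feature names, best first,
#'   support only), `support`, `center`, `scale`, `classes`, `sparsity`,
#'   `ridge`.
#' @export
slda_rank <- function(X, y, sparsity = 1e-3, ridge = 1e-2,
                      max_iter = 50, tol = 1e-6) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least two classes")
  if (any(table(y) < 2)) stop("each class needs at least two instances")
  n <- nrow(X); p <- ncol(X); K <- nlevels(y)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (all(scl == 0)) stop("all features are constant")
  scl_use <- ifelse(scl == 0, 1, scl)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl_use, "/")
  Y <- stats::model.matrix(~ y - 1)
  dpri <- colSums(Y) / n                      # diag of D = Y'Y/n
  Q <- K - 1L
  # D-orthonormal basis starting with the trivial constant score
  Theta <- matrix(1 / sqrt(sum(dpri)), nrow = K, ncol = 1)
  B <- matrix(0, nrow = p, ncol = Q,
              dimnames = list(colnames(X), NULL))
  for (q in seq_len(Q)) {
    theta <- rep(0, K); theta[q] <- 1
    proj <- Theta %*% (t(Theta) * dpri) %*% theta
    theta <- theta - drop(proj)
    theta <- theta / sqrt(sum(dpri * theta^2))
    beta <- rep(0, p)
    for (it in seq_len(max_iter)) {
      z <- drop(Y %*% theta)
      beta_new <- penalized_ls(Xs, z, sparsity, ridge)
      w <- drop(crossprod(Y, Xs %*% beta_new)) / (n * dpri)
      w <- w - drop(Theta %*% (t(Theta) * dpri) %*% w)
      nrm <- sqrt(sum(dpri * w^2))
      if (nrm < 1e-12) { beta <- beta_new; break }
      theta_new <- w / nrm
      if (sum(dpri * theta_new * theta) < 0) theta_new <- -theta_new
      done <- sqrt(sum((theta_new - theta)^2)) < tol
      theta <- theta_new
      beta <- beta_new
      if (done) break
    }
    Theta <- cbind(Theta, theta)
    B[, q] <- beta
  }
  strength <- apply(abs(B), 1, max)
  support <- which(strength > 0)
  ranking <- colnames(X)[support[order(-strength[support],
                                       support)]]
  structure(
    list(vectors = B, ranking = ranking,
         support = colnames(X)[support], center = ctr, scale = scl_use,
         classes = levels(y), sparsity = sparsity, ridge = ridge),
    class = "slda_model")
}

# elastic-net (or ridge/OLS) solve of min (1/2n)||z - Xb||^2 + penalties;
# glmnet handles p >= 2, small p falls back to closed-form ridge
penalized_ls <- function(Xs, z, sparsity, ridge) {
  p <- ncol(Xs)
  n <- nrow(Xs)
  if (p == 1 || (sparsity == 0 && ridge == 0)) {
    lam <- ridge * n
    return(drop(solve(crossprod(Xs) + diag(lam, p), crossprod(Xs, z))))
  }
  lam <- sparsity + ridge
  alpha <- if (lam > 0) sparsity / lam else 0
  fit <- glmnet::glmnet(Xs, z, alpha = alpha, lambda = lam,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-10)
  drop(as.matrix(fit$beta))
}

#' @export
print.slda_model <- function(x, ...) {
  cat("<slda_model> ", length(x$classes), " classes, ",
      ncol(x$vectors), " discriminant vector(s), support ",
      length(x$support), "/", nrow(x$vectors), " features\n", sep = "")
  if (length(x$ranking) > 0) {
    cat("  top features: ",
        paste(utils::head(x$ranking, 5), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Leave-one-subject-out cross-validated classification
#'
#' One fold per subject. Within each fold, feature standardization and the
#' sparse-LDA ranking are fitted on the training subjects only; the top
#' `top_k` ranked features feed a soft-margin SVM (linear kernel, cost 1 by
#' default), which predicts the held-out subject's instances. Accuracy is
#' the fraction of correct predictions over all held-out instances.
#'
#' @param X Feature matrix/data.frame, instances x features.
#' @param y Class labels.
#' @param subject_ids Subject of each instance; defines the folds.
#' @param classifier_params List: `kernel` (default "linear"), `cost`
#'   (default 1).
#' @param top_k Number of ranked features to keep; `NULL` (default) keeps
#'   the whole nonzero-support ranking.
#' @param slda_params List of arguments passed on to [slda_rank()].
#' @return A `classification_report`: list with `accuracy`, `confusion`,
#'   `predictions` (data.frame subject, truth, prediction), `n_folds`,
#'   `fold_rankings`.
#' @export
loso_cv <- function(X, y, subject_ids,
                    classifier_params = list(kernel = "linear", cost = 1),
                    top_k = NULL, slda_params = list()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- factor(y)
  stopifnot(nrow(X) == length(y), length(subject_ids) == length(y))
  subjects <- unique(subject_ids)
  kernel <- classifier_params$kernel %||% "linear"
  cost <- classifier_params$cost %||% 1
  preds <- vector("list", length(subjects))
  rankings <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    tr <- subject_ids != s
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < nlevels(y)) {
      stop("training fold for subject ", s, " lost a class")
    }
    model <- do.call(slda_rank,
                     c(list(X = X[tr, , drop = FALSE], y = ytr),
                       slda_params))
    feats <- model$ranking
    if (length(feats) == 0) feats <- colnames(X)
    if (!is.null(top_k)) feats <- utils::head(feats, top_k)
    scale_tr <- function(M) {
      sweep(sweep(M[, feats, drop = FALSE], 2, model$center[feats]),
            2, model$scale[feats], "/")
    }
    fit <- e1071::svm(x = scale_tr(X[tr, , drop = FALSE]), y = ytr,
                      kernel = kernel, cost = cost, scale = FALSE)
    pred <- stats::predict(fit, scale_tr(X[!tr, , drop = FALSE]))
    preds[[i]] <- data.frame(subject = s,
                             truth = as.character(y[!tr]),
                             prediction = as.character(pred))
    rankings[[i]] <- feats
  }
  predictions <- do.call(rbind, preds)
  confusion <- table(truth = factor(predictions$truth, levels(y)),
                     prediction = factor(predictions$prediction, levels(y)))
  structure(
    list(accuracy = mean(predictions$truth == predictions$prediction),
         confusion = confusion, predictions = predictions,
         n_folds = length(subjects), fold_rankings = rankings),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> ", x$n_folds, " folds, accuracy ",
      sprintf("%.4f", x$accuracy), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

# classification tasks over the four film conditions
task_conditions <- function(task) {
  switch(task,
         tender_vs_amuse = c("amusement", "tenderness"),
         anger_vs_fear = c("anger", "fear"),
         four_class = emotion_conditions(),
         stop("unknown task: ", task))
}

#' Feature-set classification experiment
#'
#' For each requested feature set and task, assembles the features from the
#' normalized band-power table and runs leave-one-subject-out SVM
#' classification with per-fold sparse-LDA feature ranking, yielding one
#' accuracy per (task, feature set) — the layout of a feature-set comparison
#' table.
#'
#' @param table A `band_power_table`.
#' @param set_ids Feature sets, default all five.
#' @param tasks Character subset of `tender_vs_amuse`, `anger_vs_fear`,
#'   `four_class`.
#' @param layout A `channel_layout`.
#' @param classifier_params,top_k,slda_params Passed to [loso_cv()].
#' @return List with `summary` (data.frame set_id, task, accuracy, n_test)
#'   and `reports` (nested list of `classification_report`).
#' @export
run_feature_set_experiment <- function(table,
                                       set_ids = feature_set_ids(),
                                       tasks = c("tender_vs_amuse",
                                                 "anger_vs_fear",
                                                 "four_class"),
                                       layout = default_layout(),
                                       classifier_params = list(
                                         kernel = "linear", cost = 1),
                                       top_k = NULL, slda_params = list()) {
  reports <- list()
  rows <- list()
  for (sid in set_ids) {
    ft <- assemble_feature_set(table, sid, layout)
    feat_cols <- setdiff(names(ft), c("subject", "condition"))
    for (task in tasks) {
      conds <- task_conditions(task)
      sub <- ft[ft$condition %in% conds, , drop = FALSE]
      if (length(unique(sub$condition)) < length(conds)) {
        warning("task ", task, " skipped: condition(s) missing")
        next
      }
      rep_ <- loso_cv(sub[, feat_cols, drop = FALSE], sub$condition,
                      sub$subject, classifier_params, top_k, slda_params)
      reports[[sid]][[task]] <- rep_
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = sid, task = task, accuracy = rep_$accuracy,
        n_test = nrow(rep_$predictions))
    }
  }
  list(summary = do.call(rbind, rows), reports = reports)
}
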
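new_stat_result <- function(statistic, df, p, effect_size = NA_real_,
                            label = "", extra = list()) {
  structure(c(list(statistic = statistic, df = df, p = p,
                   effect_size = effect_size, label = label), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$label, ": stat = ",
      signif(x$statistic, 4), ", df = ", paste(x$df, collapse = ", "),
      ", p = ", signif(x$p, 3),
      if (!is.na(x$effect_size)) paste0(", effect = ",
                                        signif(x$effect_size, 3)),
      "\n", sep = "")
  invisible(x)
}

#' Paired-samples t test with effect sizes
#'
#' Two-sided paired t test on subject-wise differences `d = x - y`:
#' `t = mean(d) / (sd(d)/sqrt(n))`, `df = n - 1`. Reports two standardized
#' effect sizes: `d_z = mean(d)/sd(d)` (the default `effect_size`) and
#' `d_av = mean(d) / ((sd(x)+sd(y))/2)`, since published paired designs use
#' either convention. Degenerate inputs: all-equal pairs give `t = 0,
#' p = 1`; zero difference variance with nonzero mean gives `t = +/-Inf,
#' p = 0`.
#'
#' @param x,y Equal-length paired numeric vectors, `n >= 2`.
#' @param label Optional comparison label.
#' @return A `stat_result` with extras `d_z`, `d_av`, `mean_diff`, `sd_diff`.
#' @export
paired_t <- function(x, y, label = "") {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
    dz <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t <- mean(d) / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
    dz <- mean(d) / sdd
  }
  dav_den <- (stats::sd(x) + stats::sd(y)) / 2
  dav <- if (dav_den == 0) NA_real_ else mean(d) / dav_den
  new_stat_result(t, n - 1, p, effect_size = dz, label = label,
                  extra = list(d_z = dz, d_av = dav, mean_diff = mean(d),
                               sd_diff = sdd, n = n))
}

#' Paired t from a printed difference summary
#'
#' Reconstructs the paired t statistic from a reported difference mean and
#' SD, as printed in summary tables: `t = mean_d / (sd_d/sqrt(n))`.
#'
#' @param mean_d,sd_d Mean and SD of the paired differences.
#' @param n Number of pairs.
#' @param label Optional label.
#' @return A `stat_result`.
#' @export
paired_t_from_summary <- function(mean_d, sd_d, n, label = "") {
  stopifnot(n >= 2, sd_d > 0)
  t <- mean_d / (sd_d / sqrt(n))
  new_stat_result(t, n - 1, 2 * stats::pt(-abs(t), df = n - 1),
                  effect_size = mean_d / sd_d, label = label,
                  extra = list(n = n))
}

#' Chi-square goodness-of-fit test
#'
#' `chi^2 = sum((O - E)^2 / E)`, `df = k - 1`, upper-tail p.
#'
#' @param observed_counts,expected_counts Non-negative counts; expected all
#'   positive, equal length.
#' @param label Optional label.
#' @return A `stat_result`.
#' @export
chi_square_gof <- function(observed_counts, expected_counts,
                           label = "") {
  stopifnot(length(observed_counts) == length(expected_counts),
            all(expected_counts > 0))
  stat <- sum((observed_counts - expected_counts)^2 / expected_counts)
  k <- length(observed_counts)
  new_stat_result(stat, k - 1, stats::pchisq(stat, k - 1,
                                             lower.tail = FALSE),
                  label = label)
}

#' Univariate 2x2 within-subject interaction test
#'
#' For a complete subject x factor-A x factor-B design (both factors
#' two-level, within subject), the interaction contrast is the per-subject
#' double difference `g_i = (A1B1 - A1B2) - (A2B1 - A2B2)`. The test is a
#' one-sample t on `g`: `F = t^2` with `df = (1, n-1)`, and partial eta
#' squared `t^2 / (t^2 + n - 1)`. (Sphericity corrections are vacuous for
#' two-level factors.)
#'
#' @param dv Numeric array `n x 2 x 2` (subjects x A x B).
#' @param label Optional label.
#' @return A `stat_result` with `effect_size` = partial eta squared.
#' @export
within_interaction_univariate <- function(dv, label = "") {
  stopifnot(length(dim(dv)) == 3, dim(dv)[2] == 2, dim(dv)[3] == 2)
  n <- dim(dv)[1]
  g <- (dv[, 1, 1] - dv[, 1, 2]) - (dv[, 2, 1] - dv[, 2, 2])
  if (stats::sd(g) == 0) {
    f <- if (mean(g) == 0) 0 else Inf
    p <- if (mean(g) == 0) 1 else 0
  } else {
    t <- mean(g) / (stats::sd(g) / sqrt(n))
    f <- t^2
    p <- stats::pf(f, 1, n - 1, lower.tail = FALSE)
  }
  eta <- f / (f + n - 1)
  new_stat_result(f, c(1, n - 1), p, effect_size = eta, label = label)
}

#' Multivariate 2x2 within-subject interaction test (Wilks lambda)
#'
#' Joint test of the interaction contrast across `p` dependent variables:
#' a one-sample Hotelling T-squared on the per-subject double-difference
#' vectors, with `Wilks lambda = 1 / (1 + T^2/(n-1))` and
#' `F = ((n - p)/p) * T^2/(n - 1)` on `(p, n - p)` df.
#'
#' @param dvs Numeric array `n x 2 x 2 x p` (subjects x A x B x DV).
#' @param label Optional label.
#' @return A `stat_result` (statistic = F) with extras `T2`, `lambda`;
#'   `effect_size` = partial eta squared `1 - lambda`.
#' @export
within_interaction_multivariate <- function(dvs, label = "") {
  stopifnot(length(dim(dvs)) == 4, dim(dvs)[2] == 2, dim(dvs)[3] == 2)
  n <- dim(dvs)[1]
  p <- dim(dvs)[4]
  if (n <= p) stop("need more subjects than dependent variables")
  g <- sapply(seq_len(p), function(j) {
    (dvs[, 1, 1, j] - dvs[, 1, 2, j]) - (dvs[, 2, 1, j] - dvs[, 2, 2, j])
  })
  gbar <- colMeans(g)
  S <- stats::cov(g)
  if (all(g == 0)) {
    # identically-zero contrasts: T2 = 0 by convention
    return(new_stat_result(0, c(p, n - p), 1, effect_size = 0,
                           label = label, extra = list(T2 = 0, lambda = 1)))
  }
  sol <- tryCatch(solve(S, gbar),
                  error = function(e)
                    stop("singular covariance of interaction contrasts"))
  t2 <- n * drop(t(gbar) %*% sol)
  lambda <- 1 / (1 + t2 / (n - 1))
  f <- ((n - p) / p) * t2 / (n - 1)
  new_stat_result(f, c(p, n - p),
                  stats::pf(f, p, n - p, lower.tail = FALSE),
                  effect_size = 1 - lambda, label = label,
                  extra = list(T2 = t2, lambda = lambda))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection on the covariates plus an intercept; two-sided t-based p with
#' `df = n - k - 2` for `k` covariates. With no covariates this is the
#' ordinary Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix/data.frame with `n` rows, or `NULL`.
#' @param label Optional label.
#' @return A `stat_result` (statistic = r) with extra `t`.
#' @export
partial_correlation <- function(x, y, covariates = NULL, label = "") {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- 0L
  if (!is.null(covariates)) {
    z <- as.matrix(covariates)
    stopifnot(nrow(z) == n)
    k <- ncol(z)
    x <- stats::resid(stats::lm.fit(cbind(1, z), x))
    y <- stats::resid(stats::lm.fit(cbind(1, z), y))
  }
  if (n <= k + 2) stop("need n > #covariates + 2")
  r <- stats::cor(x, y)
  df <- n - k - 2
  t <- r * sqrt(df / (1 - r^2))
  new_stat_result(r, df, 2 * stats::pt(-abs(t), df), effect_size = r,
                  label = label, extra = list(t = t))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' adjusted values never fall below the raw ones.
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Stepwise multiple linear regression by partial-F p values
#'
#' Forward entry of the candidate with the smallest partial-F p below
#' `p_enter`, then backward removal of any entered predictor whose
#' partial-F p exceeds `p_remove`, iterated until stable. Reports
#' unstandardized coefficients with standard errors, standardized betas,
#' adjusted R-squared, and the overall model F and p.
#'
#' @param candidates Numeric matrix or data.frame of candidate predictors
#'   (named columns).
#' @param y Response vector.
#' @param p_enter,p_remove Entry/removal thresholds; `p_enter <= p_remove`
#'   is required (prevents cycling). Defaults 0.05 / 0.10.
#' @return A `regression_model`: list with `predictors`, `coefficients`
#'   (data.frame term, B, SE, beta, t, p), `adj_r_squared`, `F`, `df`,
#'   `p_value`, `n`.
#' @export
stepwise_regression <- function(candidates, y, p_enter = 0.05,
                                p_remove = 0.10) {
  X <- as.matrix(candidates)
  rownames(X) <- NULL
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (p_enter > p_remove) {
    stop("p_enter must be <= p_remove (prevents cycling)")
  }
  if (stats::var(y) == 0) {
    # constant response: nothing to explain, intercept-only model
    coefs <- data.frame(term = "(Intercept)", B = mean(y), SE = 0,
                        beta = NA_real_, t = NA_real_, p = NA_real_)
    return(structure(list(predictors = character(), coefficients = coefs,
                          adj_r_squared = 0, F = NA_real_,
                          df = c(0, n - 1), p_value = NA_real_, n = n),
                     class = "regression_model"))
  }
  selected <- character()
  partial_p <- function(sel) {
    # p value of each term's t test in the model with predictors `sel`
    fit <- stats::lm(y ~ ., data = data.frame(y = y, X[, sel, drop = FALSE],
                                              check.names = FALSE))
    cf <- summary(fit)$coefficients
    cf[-1, 4]
  }
  entry_p <- function(cand, sel) {
    fit <- stats::lm(y ~ ., data = data.frame(
      y = y, X[, c(sel, cand), drop = FALSE], check.names = FALSE))
    cf <- summary(fit)$coefficients
    cf[nrow(cf), 4]
  }
  max_iter <- 4L * ncol(X)
  for (it in seq_len(max_iter + 1L)) {
    if (it > max_iter) stop("stepwise selection failed to converge")
    changed <- FALSE
    pool <- setdiff(colnames(X), selected)
    if (length(pool) > 0 && n > length(selected) + 2) {
      ps <- vapply(pool, entry_p, 0, sel = selected)
      ps <- ps[!is.na(ps)]
      if (length(ps) > 0 && min(ps) < p_enter) {
        selected <- c(selected, names(ps)[which.min(ps)])
        changed <- TRUE
      }
    }
    if (length(selected) > 0) {
      ps <- partial_p(selected)
      if (length(ps) > 0 && max(ps) > p_remove) {
        worst <- names(ps)[which.max(ps)]
        selected <- setdiff(selected, worst)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(selected) == 0) {
    fit <- stats::lm(y ~ 1)
    coefs <- data.frame(term = "(Intercept)",
                        B = mean(y), SE = stats::sd(y) / sqrt(n),
                        beta = NA_real_, t = NA_real_, p = NA_real_)
    out <- list(predictors = character(), coefficients = coefs,
                adj_r_squared = 0, F = NA_real_, df = c(0, n - 1),
                p_value = NA_real_, n = n)
  } else {
    fit <- stats::lm(y ~ ., data = data.frame(
      y = y, X[, selected, drop = FALSE], check.names = FALSE))
    sm <- summary(fit)
    cf <- sm$coefficients
    beta <- c(NA_real_,
              cf[-1, 1] * apply(X[, selected, drop = FALSE], 2, stats::sd) /
                stats::sd(y))
    coefs <- data.frame(term = rownames(cf), B = cf[, 1], SE = cf[, 2],
                        beta = beta, t = cf[, 3], p = cf[, 4],
                        row.names = NULL)
    out <- list(predictors = selected, coefficients = coefs,
                adj_r_squared = sm$adj.r.squared,
                F = unname(sm$fstatistic[1]),
                df = unname(sm$fstatistic[2:3]),
                p_value = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                    sm$fstatistic[3], lower.tail = FALSE),
                n = n)
  }
  class(out) <- "regression_model"
  out
}

#' @export
print.regression_model <- function(x, ...) {
  cat("<regression_model> ", length(x$predictors), " predictor(s)",
      if (length(x$predictors) > 0)
        paste0(": ", paste(x$predictors, collapse = ", ")),
      "\n  adj R^2 = ", signif(x$adj_r_squared, 3), sep = "")
  if (!is.na(x$F)) {
    cat(", F(", x$df[1], ",", x$df[2], ") = ", signif(x$F, 4),
        ", p = ", signif(x$p_value, 3), sep = "")
  }
  cat("\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}
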
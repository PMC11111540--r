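#' Cross-validation configuration
#'
#' Bundles the hyperparameter grids and fold structure used by
#' \code{\link{risk_enet}} and \code{\link{nested_cv}}. Defaults follow the
#' evaluation protocol used throughout the package: an 11-step even grid for
#' the L1 mixing ratio on [0, 1], an 8-step exponential grid for the penalty
#' magnitude on [1e-5, 100] (i.e. \code{10^seq(-5, 2, length.out = 8)}),
#' 10 outer folds repeated 10 times with reshuffling, 10 inner folds, and no
#' predictor standardization (standardizing penalizes SVD-based embeddings,
#' whose variance is concentrated in leading dimensions).
#'
#' @param outer_folds number of outer CV folds.
#' @param repeats number of repeats, each with a fresh shuffle.
#' @param inner_folds folds for inner (hyperparameter-selection) CV.
#' @param l1_ratio_grid grid of elastic-net mixing ratios in [0, 1].
#' @param alpha_grid grid of penalty magnitudes (> 0).
#' @param seed master seed; all shuffling seeds are derived from it.
#' @param standardize standardize predictors inside the elastic net.
#' @return object of class \code{"cv_config"}.
#' @export
cv_config <- function(outer_folds = 10, repeats = 10, inner_folds = 10,
                      l1_ratio_grid = seq(0, 1, length.out = 11),
                      alpha_grid = 10^seq(-5, 2, length.out = 8),
                      seed = 1, standardize = FALSE) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, repeats >= 1,
            all(l1_ratio_grid >= 0 & l1_ratio_grid <= 1),
            all(alpha_grid > 0), length(seed) == 1)
  structure(list(outer_folds = as.integer(outer_folds),
                 repeats = as.integer(repeats),
                 inner_folds = as.integer(inner_folds),
                 l1_ratio_grid = as.numeric(l1_ratio_grid),
                 alpha_grid = as.numeric(alpha_grid),
                 seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "cv_config")
}

as_design_matrix <- function(x) {
  if (inherits(x, "ensemble_matrix")) x$matrix
  else as.matrix(x)
}

# fit one glmnet path per mixing ratio; return validation predictions for the
# full (l1_ratio x alpha) grid as a list of n_val x n_alpha matrices
enet_grid_predict <- function(xtr, ytr, xval, config) {
  lam <- sort(config$alpha_grid, decreasing = TRUE)
  ord <- match(config$alpha_grid, lam)
  lapply(config$l1_ratio_grid, function(l1) {
    fit <- glmnet::glmnet(xtr, ytr, alpha = l1, lambda = lam,
                          standardize = config$standardize)
    p <- stats::predict(fit, xval, s = lam)
    p[, ord, drop = FALSE]   # columns back in alpha_grid order
  })
}

# grid search by k-fold CV: mean held-out R^2 per (l1_ratio, alpha), highest
# wins; ties resolved by first grid position (l1 outer, alpha inner)
select_hyperparams <- function(x, y, config, folds = config$inner_folds) {
  n <- length(y)
  fold_of <- rep(seq_len(folds), length.out = n)
  nl1 <- length(config$l1_ratio_grid)
  nal <- length(config$alpha_grid)
  score <- array(NA_real_, c(folds, nl1, nal))
  for (f in seq_len(folds)) {
    val <- which(fold_of == f)
    tr <- which(fold_of != f)
    if (stats::var(y[val]) == 0) next
    preds <- enet_grid_predict(x[tr, , drop = FALSE], y[tr],
                               x[val, , drop = FALSE], config)
    for (i in seq_len(nl1))
      for (j in seq_len(nal))
        score[f, i, j] <- r_squared(y[val], preds[[i]][, j])
  }
  mean_score <- apply(score, c(2, 3), mean, na.rm = TRUE)
  best <- which(mean_score == max(mean_score), arr.ind = TRUE)[1, ]
  list(l1_ratio = config$l1_ratio_grid[best[1]],
       alpha = config$alpha_grid[best[2]],
       cv_score = mean_score[best[1], best[2]])
}

fit_enet_at <- function(x, y, l1_ratio, alpha, config) {
  lam <- sort(unique(c(config$alpha_grid, alpha)), decreasing = TRUE)
  glmnet::glmnet(x, y, alpha = l1_ratio, lambda = lam,
                 standardize = config$standardize)
}

#' Fit a final elastic-net risk model
#'
#' Selects hyperparameters by (non-nested) k-fold cross-validation over the
#' full grid, then refits the elastic net on all data at the selected pair.
#' Use the resulting model to generalize predictions beyond the rated terms
#' (e.g. to every token of an embedding vocabulary).
#'
#' The penalty parameterization matches the convention used by
#' scikit-learn's ElasticNet: \code{alpha} is the overall penalty magnitude
#' and \code{l1_ratio} the L1/L2 mix (glmnet's \code{lambda} and
#' \code{alpha}, respectively).
#'
#' @param x design matrix or \code{ensemble_matrix} (terms x predictors).
#' @param y numeric response (mean risk ratings), aligned with rows of x.
#' @param config a \code{\link{cv_config}}.
#' @return object of class \code{"risk_enet"} with coefficients, intercept,
#'   selected hyperparameters and (when x is an ensemble) the block spans.
#' @export
risk_enet <- function(x, y, config = cv_config()) {
  spans <- if (inherits(x, "ensemble_matrix")) x$block_spans else NULL
  terms <- if (inherits(x, "ensemble_matrix")) x$terms else rownames(x)
  xm <- as_design_matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(xm) == length(y))
  if (stats::var(y) == 0) stop("constant response: R^2 undefined")
  hp <- select_hyperparams(xm, y, config)
  fit <- fit_enet_at(xm, y, hp$l1_ratio, hp$alpha, config)
  beta <- as.numeric(stats::coef(fit, s = hp$alpha))
  structure(list(coefficients = stats::setNames(beta[-1], colnames(xm)),
                 intercept = beta[1],
                 hyperparams = list(alpha = hp$alpha,
                                    l1_ratio = hp$l1_ratio),
                 cv_score = hp$cv_score,
                 block_spans = spans, terms = terms,
                 config = config, call = match.call()),
            class = "risk_enet")
}

#' @export
print.risk_enet <- function(x, ...) {
  cat("Elastic-net risk model\n")
  cat(sprintf("  predictors: %d (%d nonzero)\n", length(x$coefficients),
              sum(x$coefficients != 0)))
  cat(sprintf("  alpha = %.3g, l1_ratio = %.2f (CV R^2 = %.3f)\n",
              x$hyperparams$alpha, x$hyperparams$l1_ratio, x$cv_score))
  invisible(x)
}

#' @export
coef.risk_enet <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Predict from a fitted risk model
#'
#' @param object a \code{risk_enet}.
#' @param newx matrix (or \code{ensemble_matrix}) with the same number of
#'   columns as the training design matrix.
#' @param ... unused.
#' @return numeric vector of predicted risk ratings.
#' @export
predict.risk_enet <- function(object, newx, ...) {
  m <- as_design_matrix(newx)
  if (ncol(m) != length(object$coefficients))
    stop("newx has ", ncol(m), " columns; model expects ",
         length(object$coefficients))
  drop(m %*% object$coefficients) + object$intercept
}

#' Nested repeated cross-validated evaluation
#'
#' Estimates out-of-sample predictive accuracy of the elastic net on a
#' feature matrix by nested k-fold cross-validation repeated with fresh
#' shuffles. Within each repeat the rows are shuffled with a seed derived
#' from the master seed and split into \code{outer_folds} folds; on each
#' outer training set the hyperparameter pair is selected by inner k-fold CV
#' over the full grid, the model is refit, and R-squared is computed on the
#' held-out outer fold. All \code{repeats * outer_folds} fold scores are
#' retained, along with each observation's out-of-fold prediction per repeat.
#'
#' @param x design matrix or \code{ensemble_matrix}.
#' @param y numeric response aligned with rows of x.
#' @param config a \code{\link{cv_config}}.
#' @return object of class \code{"risk_cv"}: \code{fold_r2}
#'   (repeats x folds), \code{grand_mean_r2}, \code{ci_low}/\code{ci_high}
#'   (normal-theory 95\% interval over fold scores; see
#'   \code{\link{adjusted_ci}} for multi-model intervals),
#'   \code{chosen} (per-fold hyperparameters), \code{oof}
#'   (n x repeats out-of-fold predictions), \code{residuals}
#'   (observed - mean out-of-fold prediction).
#' @export
nested_cv <- function(x, y, config = cv_config()) {
  xm <- as_design_matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(xm) == n)
  if (n < 2 * config$outer_folds)
    stop("need at least ", 2 * config$outer_folds, " observations")
  if (stats::var(y) == 0) stop("constant response: R^2 undefined")
  seeds <- derive_seeds(config$seed, config$repeats)
  fold_r2 <- matrix(NA_real_, config$repeats, config$outer_folds)
  oof <- matrix(NA_real_, n, config$repeats)
  chosen <- vector("list", config$repeats * config$outer_folds)
  for (r in seq_len(config$repeats)) {
    set.seed(seeds[r])
    perm <- sample.int(n)
    fold_of <- integer(n)
    fold_of[perm] <- rep(seq_len(config$outer_folds), length.out = n)
    for (f in seq_len(config$outer_folds)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      hp <- select_hyperparams(xm[train, , drop = FALSE], y[train], config)
      fit <- fit_enet_at(xm[train, , drop = FALSE], y[train],
                         hp$l1_ratio, hp$alpha, config)
      pred <- drop(stats::predict(fit, xm[test, , drop = FALSE],
                                  s = hp$alpha))
      fold_r2[r, f] <- r_squared(y[test], pred)
      oof[test, r] <- pred
      chosen[[(r - 1L) * config$outer_folds + f]] <-
        data.frame(repeat_ = r, fold = f, alpha = hp$alpha,
                   l1_ratio = hp$l1_ratio)
    }
  }
  scores <- as.vector(t(fold_r2))
  gm <- mean(scores)
  se <- stats::sd(scores) / sqrt(length(scores))
  z <- stats::qnorm(0.975)
  terms <- if (inherits(x, "ensemble_matrix")) x$terms else rownames(xm)
  res <- y - rowMeans(oof)
  if (!is.null(terms)) names(res) <- terms
  structure(list(fold_r2 = fold_r2, per_fold_r2 = scores,
                 grand_mean_r2 = gm, ci_low = gm - z * se,
                 ci_high = gm + z * se,
                 chosen = do.call(rbind, chosen),
                 oof = oof, residuals = res, y = y, terms = terms,
                 config = config, call = match.call()),
            class = "risk_cv")
}

#' @export
print.risk_cv <- function(x, ...) {
  cat("Nested cross-validated elastic net\n")
  cat(sprintf("  %d folds x %d repeats (%d fold scores)\n",
              x$config$outer_folds, x$config$repeats,
              length(x$per_fold_r2)))
  cat(sprintf("  grand mean R^2 = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$grand_mean_r2, x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
summary.risk_cv <- function(object, ...) {
  hp <- object$chosen
  out <- list(grand_mean_r2 = object$grand_mean_r2,
              ci = c(object$ci_low, object$ci_high),
              fold_r2_range = range(object$per_fold_r2),
              per_repeat_mean = rowMeans(object$fold_r2),
              alpha_table = table(hp$alpha),
              l1_ratio_table = table(hp$l1_ratio))
  class(out) <- "summary.risk_cv"
  out
}

#' @export
print.summary.risk_cv <- function(x, ...) {
  cat(sprintf("Grand mean R^2: %.4f  [%.4f, %.4f]\n", x$grand_mean_r2,
              x$ci[1], x$ci[2]))
  cat(sprintf("Fold R^2 range: [%.3f, %.3f]\n", x$fold_r2_range[1],
              x$fold_r2_range[2]))
  cat("Selected alpha frequencies:\n"); print(x$alpha_table)
  cat("Selected l1_ratio frequencies:\n"); print(x$l1_ratio_table)
  invisible(x)
}

#' @export
residuals.risk_cv <- function(object, ...) object$residuals

#' @export
plot.risk_cv <- function(x, ...) {
  graphics::boxplot(t(x$fold_r2), xlab = "repeat",
                    ylab = expression(R^2), ...)
  graphics::abline(h = x$grand_mean_r2, lty = 2)
  invisible(x)
}

#' Out-of-fold predictions and residuals
#'
#' Runs \code{\link{nested_cv}} and returns each term's out-of-fold
#' predictions (one per repeat; every term sits in exactly one test fold per
#' repeat) and the residual, observed minus mean out-of-fold prediction.
#' Cross-validated residuals avoid the optimistic shrinkage of in-sample
#' residuals and are the default input to the interpretability analysis.
#'
#' @inheritParams nested_cv
#' @return list with \code{oof} (n x repeats matrix), \code{mean_prediction},
#'   \code{residuals} (named by term when available) and the full
#'   \code{risk_cv} object under \code{cv}.
#' @export
oof_predictions <- function(x, y, config = cv_config()) {
  cvres <- nested_cv(x, y, config)
  list(oof = cvres$oof, mean_prediction = rowMeans(cvres$oof),
       residuals = cvres$residuals, cv = cvres)
}

#' Adjusted confidence intervals for model comparison
#'
#' Computes within-design (repeated-measures) 95\% confidence intervals for
#' several models evaluated on the same cross-validation partitioning. Each
#' fold's scores are centered across models to remove the shared fold
#' effect, the small-sample correction factor \eqn{\sqrt{m/(m-1)}} for m
#' models is applied to the resulting deviations, and a normal-theory
#' interval is formed from the adjusted per-fold scores.
#'
#' @param fold_scores matrix of per-fold R-squared values, one column per
#'   model, rows aligned across models (same fold partitioning).
#' @param conf confidence level, default 0.95.
#' @return data.frame with one row per model: \code{mean}, \code{low},
#'   \code{high}.
#' @export
adjusted_ci <- function(fold_scores, conf = 0.95) {
  S <- as.matrix(fold_scores)
  n <- nrow(S); m <- ncol(S)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (m == 1) {
    warning("single model supplied; returning unadjusted interval")
    se <- stats::sd(S[, 1]) / sqrt(n)
    return(data.frame(mean = mean(S[, 1]), low = mean(S[, 1]) - z * se,
                      high = mean(S[, 1]) + z * se,
                      row.names = colnames(S) %||% "model1"))
  }
  centered <- S - rowMeans(S) + mean(S)
  corr <- sqrt(m / (m - 1))
  means <- colMeans(S)
  se <- apply(centered, 2, stats::sd) * corr / sqrt(n)
  data.frame(mean = means, low = means - z * se, high = means + z * se,
             row.names = colnames(S) %||% paste0("model", seq_len(m)))
}
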
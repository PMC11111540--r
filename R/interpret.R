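#' Norm-association report
#'
#' Internal constructor shared by \code{\link{baseline_norm_association}} and
#' \code{\link{residual_norm_association}}: absolute Pearson correlation of a
#' target vector with each norm, 95\% CIs via the Fisher z transform, and
#' per-group mean absolute correlations. Norms constant over the shared terms
#' are flagged and excluded from group means.
#'
#' @keywords internal
norm_association <- function(target, norms_mat, groups) {
  n <- length(target)
  per_norm <- do.call(rbind, lapply(colnames(norms_mat), function(nm) {
    v <- norms_mat[, nm]
    if (stats::sd(v) == 0) {
      return(data.frame(norm = nm, group = unname(groups[nm]),
                        abs_r = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, constant = TRUE))
    }
    r <- stats::cor(target, v)
    zr <- atanh(min(1 - 1e-15, max(-1 + 1e-15, r)))
    se <- 1 / sqrt(n - 3)
    # CI of |r|: when the r interval straddles 0 the lower bound of |r| is 0
    lo <- tanh(zr - stats::qnorm(0.975) * se)
    hi <- tanh(zr + stats::qnorm(0.975) * se)
    ci_abs <- if (lo <= 0 && hi >= 0) c(0, max(abs(lo), abs(hi)))
              else sort(abs(c(lo, hi)))
    data.frame(norm = nm, group = unname(groups[nm]), abs_r = abs(r),
               ci_low = ci_abs[1], ci_high = ci_abs[2], constant = FALSE)
  }))
  ok <- per_norm[!per_norm$constant, ]
  per_group <- if (nrow(ok))
    stats::aggregate(abs_r ~ group, data = ok, FUN = mean)
  else data.frame(group = character(), abs_r = numeric())
  names(per_group)[2] <- "mean_abs_r"
  structure(list(per_norm = per_norm, per_group = per_group, n = n),
            class = "norm_association")
}

#' @export
print.norm_association <- function(x, ...) {
  cat("Norm association report (n =", x$n, "terms)\n")
  print(x$per_group, row.names = FALSE)
  if (!is.null(x$shared_variance))
    cat(sprintf("Shared variance (all norms jointly): %.1f%%\n",
                100 * x$shared_variance))
  invisible(x)
}

align_norm_terms <- function(norms, terms) {
  idx <- match(terms, norms$token)
  keep <- !is.na(idx)
  gmap <- attr(norms, "norm_groups")
  m <- as.matrix(norms[idx[keep], setdiff(names(norms), "token"),
                       drop = FALSE])
  rownames(m) <- terms[keep]
  list(mat = m, groups = gmap, keep = keep)
}

#' Baseline association between word norms and risk ratings
#'
#' Correlates every norm with the mean risk ratings over the terms shared
#' between the two tables, reports per-group (affect, concreteness,
#' frequency) mean absolute correlations, and estimates the variance the
#' norms jointly share with risk perception by predicting risk means from
#' all norms with the same cross-validated elastic-net protocol used for the
#' embedding models (set \code{shared_variance = "in_sample"} for the
#' in-sample multiple R-squared, or \code{"none"} to skip it).
#'
#' @param norms a \code{norm_table} from \code{\link{read_norms}}.
#' @param ratings a \code{ratings_table} from \code{\link{read_ratings}}.
#' @param config a \code{\link{cv_config}} for the shared-variance fit.
#' @param shared_variance one of \code{"cv"}, \code{"in_sample"},
#'   \code{"none"}.
#' @return a \code{norm_association} report; field \code{shared_variance}
#'   is a proportion in [0, 1] unless skipped.
#' @export
baseline_norm_association <- function(norms, ratings, config = cv_config(),
                                      shared_variance = c("cv", "in_sample",
                                                          "none")) {
  shared_variance <- match.arg(shared_variance)
  al <- align_norm_terms(norms, ratings$risk_term)
  if (nrow(al$mat) < 3)
    stop("fewer than 3 terms shared between norms and ratings")
  y <- ratings$risk_mean[al$keep]
  rep <- norm_association(y, al$mat, al$groups)
  nonconst <- rep$per_norm$norm[!rep$per_norm$constant]
  if (shared_variance == "cv") {
    cvres <- nested_cv(al$mat[, nonconst, drop = FALSE], y, config)
    rep$shared_variance <- max(0, min(1, cvres$grand_mean_r2))
  } else if (shared_variance == "in_sample") {
    fit <- stats::lm(y ~ al$mat[, nonconst, drop = FALSE])
    rep$shared_variance <- summary(fit)$r.squared
  }
  rep
}

#' Correlate model residuals with word norms
#'
#' Residual correlations quantify systematic risk-perception variance a
#' model fails to capture but a norm does: a norm retaining a sizable
#' absolute correlation with the residuals marks a dimension missing from
#' the model's features.
#'
#' @param residuals named numeric vector (term -> residual), e.g. from
#'   \code{\link{oof_predictions}}.
#' @param norms a \code{norm_table}.
#' @return a \code{norm_association} report.
#' @export
residual_norm_association <- function(residuals, norms) {
  if (is.null(names(residuals)))
    stop("residuals must be named by term")
  al <- align_norm_terms(norms, names(residuals))
  if (nrow(al$mat) < 3)
    stop("fewer than 3 residual terms found in the norm table")
  norm_association(unname(residuals[al$keep]), al$mat, al$groups)
}

#' Drops in norm correlations across modelling stages
#'
#' Given an ordered list of norm-association reports (e.g. baseline risk
#' variance, psychometric residuals, ensemble residuals), computes the drop
#' in mean absolute correlation per norm group between consecutive stages:
#' \eqn{\Delta(\mathrm{group}, i \to i+1) = \bar{|r|}_i - \bar{|r|}_{i+1}}.
#'
#' @param stages named or unnamed list of \code{norm_association} reports
#'   over identical norm sets.
#' @return data.frame with columns \code{group}, \code{from}, \code{to},
#'   \code{delta}.
#' @export
drop_analysis <- function(stages) {
  stopifnot(is.list(stages), length(stages) >= 2)
  nms <- names(stages) %||% paste0("stage", seq_along(stages))
  norm_sets <- lapply(stages, function(s) sort(s$per_norm$norm))
  for (i in seq_along(stages)[-1])
    if (!identical(norm_sets[[i]], norm_sets[[1]]))
      stop("stage ", i, " has a different norm set than stage 1")
  out <- list()
  for (i in seq_len(length(stages) - 1)) {
    a <- stages[[i]]$per_group; b <- stages[[i + 1]]$per_group
    merged <- merge(a, b, by = "group", suffixes = c("_a", "_b"))
    out[[i]] <- data.frame(group = merged$group, from = nms[i],
                           to = nms[i + 1],
                           delta = merged$mean_abs_r_a - merged$mean_abs_r_b)
  }
  do.call(rbind, out)
}
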
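test_that("default configuration spans the 88-point hyperparameter grid", {
  cfg <- cv_config()
  expect_length(cfg$l1_ratio_grid, 11)
  expect_length(cfg$alpha_grid, 8)
  expect_equal(length(cfg$l1_ratio_grid) * length(cfg$alpha_grid), 88)
  expect_equal(range(cfg$l1_ratio_grid), c(0, 1))
  expect_equal(cfg$alpha_grid[1], 1e-5)
  expect_equal(cfg$alpha_grid[8], 100)
  expect_equal(diff(log10(cfg$alpha_grid)), rep(1, 7))
  expect_false(cfg$standardize)
  expect_error(cv_config(outer_folds = 1), "outer_folds")
})

test_that("noiseless planted linear data is recovered almost perfectly", {
  set.seed(31)
  n <- 500; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + 3
  cfg <- cv_config(repeats = 2, seed = 31)
  cvres <- nested_cv(X, y, cfg)
  expect_gte(cvres$grand_mean_r2, 0.99)
  # out-of-fold residuals vanish in the noiseless limit
  expect_lt(max(abs(cvres$residuals)), 0.2 * sd(y))
  fit <- risk_enet(X, y, cfg)
  cosine <- sum(fit$coefficients * beta) /
    sqrt(sum(fit$coefficients^2) * sum(beta^2))
  expect_gte(cosine, 0.99)
})

test_that("permuted labels yield no out-of-sample signal", {
  set.seed(32)
  n <- 150; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  y <- sample(drop(X %*% rnorm(p)))
  cvres <- nested_cv(X, y, cv_config(repeats = 2, seed = 32))
  expect_lte(cvres$grand_mean_r2, 0.05)
})

test_that("the heavy-shrinkage limit zeroes the coefficients", {
  set.seed(33)
  X <- scale(matrix(rnorm(60 * 5), 60, 5))
  y <- drop(scale(rnorm(60)))
  cfg <- cv_config(alpha_grid = 100, l1_ratio_grid = c(0.5, 1), seed = 33)
  fit <- risk_enet(X, y, cfg)
  expect_lt(max(abs(fit$coefficients)), 1e-6)
})

test_that("constant response is rejected", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(nested_cv(X, rep(1, 20), cv_config(repeats = 1)), "constant")
  expect_error(risk_enet(X, rep(2, 20)), "constant")
})

test_that("every term receives one out-of-fold prediction per repeat", {
  set.seed(34)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("t", 1:n), NULL))
  y <- drop(X %*% c(1, -1, 2, 0)) + rnorm(n, sd = 0.3)
  cfg <- cv_config(outer_folds = 5, repeats = 3, inner_folds = 4,
                   seed = 34)
  res <- oof_predictions(X, y, cfg)
  expect_equal(dim(res$oof), c(n, 3))
  expect_false(anyNA(res$oof))
  expect_named(res$residuals, paste0("t", 1:n))
  expect_equal(res$residuals, y - res$mean_prediction,
               ignore_attr = TRUE)
})

test_that("identical seeds give bit-identical cross-validation results", {
  set.seed(35)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(80, sd = 0.5)
  cfg <- cv_config(outer_folds = 4, repeats = 2, inner_folds = 3, seed = 99)
  a <- nested_cv(X, y, cfg)
  b <- nested_cv(X, y, cfg)
  expect_identical(a$fold_r2, b$fold_r2)
  expect_identical(a$oof, b$oof)
  expect_identical(a$chosen, b$chosen)
  # a different seed reshuffles the folds
  c <- nested_cv(X, y, cv_config(outer_folds = 4, repeats = 2,
                                 inner_folds = 3, seed = 100))
  expect_false(identical(a$fold_r2, c$fold_r2))
})

test_that("adjusted confidence intervals match a hand-worked table", {
  # 3 folds x 2 models, worked independently:
  # S = [0.70 0.80; 0.60 0.75; 0.65 0.85]
  # row means: 0.75, 0.675, 0.75 ; grand mean 0.725
  # centered col 1: 0.70-0.75+0.725, 0.60-0.675+0.725, 0.65-0.75+0.725
  #               = 0.675, 0.650, 0.625 -> sd = 0.025
  # correction sqrt(2/1) -> se = 0.025*sqrt(2)/sqrt(3)
  S <- cbind(m1 = c(0.70, 0.60, 0.65), m2 = c(0.80, 0.75, 0.85))
  ci <- adjusted_ci(S)
  se1 <- 0.025 * sqrt(2) / sqrt(3)
  expect_equal(ci["m1", "mean"], 0.65, tolerance = 1e-10)
  expect_equal(ci["m1", "low"], 0.65 - qnorm(0.975) * se1, tolerance = 1e-10)
  expect_equal(ci["m1", "high"], 0.65 + qnorm(0.975) * se1, tolerance = 1e-10)
  # column 2 centered: 0.775, 0.80, 0.85... recompute: 0.80-0.75, 0.75-0.675,
  # 0.85-0.75 each +0.725 -> 0.775, 0.80, 0.825 -> sd = 0.025
  se2 <- 0.025 * sqrt(2) / sqrt(3)
  expect_equal(ci["m2", "low"], 0.80 - qnorm(0.975) * se2, tolerance = 1e-10)
})

test_that("adjusted CI degenerate cases behave as declared", {
  S <- cbind(a = c(0.7, 0.6, 0.65), b = c(0.7, 0.6, 0.65))
  ci <- adjusted_ci(S)
  # identical models: identical (zero-width) intervals
  expect_equal(ci["a", ], ci["b", ], ignore_attr = TRUE)
  expect_equal(ci["a", "low"], ci["a", "high"])
  expect_warning(one <- adjusted_ci(S[, 1, drop = FALSE]), "single model")
  expect_equal(one$mean, 0.65)
})
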
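test_that("a norm equal to the risk means correlates perfectly", {
  set.seed(41)
  y <- rnorm(50)
  terms <- paste0("t", 1:50)
  nt <- make_norm_table(terms, cbind(valence = y, frequency = rnorm(50)))
  rt <- make_ratings_table(terms, y)
  rep <- baseline_norm_association(nt, rt, shared_variance = "none")
  expect_equal(rep$per_norm$abs_r[rep$per_norm$norm == "valence"], 1)
  expect_setequal(rep$per_norm$group, c("affect", "frequency"))
})

test_that("norms orthogonalized against residuals have zero correlation", {
  set.seed(42)
  res <- setNames(rnorm(80), paste0("t", 1:80))
  raw <- matrix(rnorm(80 * 3), 80)
  orth <- apply(raw, 2, function(v) {
    v <- v - mean(v)
    r <- res - mean(res)
    v - sum(v * r) / sum(r * r) * r
  })
  colnames(orth) <- c("fear", "anger", "concreteness")
  nt <- make_norm_table(names(res), orth)
  rep <- residual_norm_association(res, nt)
  expect_true(all(rep$per_norm$abs_r <= 1e-10))
  # and a norm equal to the residual vector correlates perfectly
  nt2 <- make_norm_table(names(res), cbind(fear = unname(res)))
  expect_equal(residual_norm_association(res, nt2)$per_norm$abs_r, 1)
})

test_that("constant norms are flagged and excluded from group means", {
  set.seed(43)
  y <- rnorm(30)
  terms <- paste0("t", 1:30)
  nt <- make_norm_table(terms, cbind(valence = y + rnorm(30),
                                     fear = rep(2, 30)))
  rep <- baseline_norm_association(nt, make_ratings_table(terms, y),
                                   shared_variance = "none")
  expect_true(rep$per_norm$constant[rep$per_norm$norm == "fear"])
  expect_equal(rep$per_group$mean_abs_r,
               rep$per_norm$abs_r[rep$per_norm$norm == "valence"])
})

test_that("group means are convex combinations of member correlations", {
  set.seed(44)
  y <- rnorm(100)
  terms <- paste0("t", 1:100)
  m <- sapply(c("valence", "fear", "anger", "frequency", "familiarity",
                "concreteness"), function(nm) 0.5 * y + rnorm(100))
  rep <- baseline_norm_association(make_norm_table(terms, m),
                                   make_ratings_table(terms, y),
                                   shared_variance = "none")
  for (g in unique(rep$per_group$group)) {
    members <- rep$per_norm$abs_r[rep$per_norm$group == g]
    gm <- rep$per_group$mean_abs_r[rep$per_group$group == g]
    expect_gte(gm, min(members)); expect_lte(gm, max(members))
  }
})

test_that("drop analysis matches hand arithmetic and is antisymmetric", {
  set.seed(45)
  y <- rnorm(60); terms <- paste0("t", 1:60)
  m1 <- cbind(valence = y + rnorm(60, sd = 0.5), frequency = rnorm(60))
  m2 <- cbind(valence = y + rnorm(60, sd = 2), frequency = rnorm(60))
  s1 <- baseline_norm_association(make_norm_table(terms, m1),
                                  make_ratings_table(terms, y),
                                  shared_variance = "none")
  s2 <- baseline_norm_association(make_norm_table(terms, m2),
                                  make_ratings_table(terms, y),
                                  shared_variance = "none")
  d <- drop_analysis(list(baseline = s1, model = s2))
  for (g in d$group) {
    a <- s1$per_group$mean_abs_r[s1$per_group$group == g]
    b <- s2$per_group$mean_abs_r[s2$per_group$group == g]
    expect_equal(d$delta[d$group == g], a - b)
  }
  # identical stages give zero drops; reversing the order flips the sign
  expect_true(all(drop_analysis(list(s1, s1))$delta == 0))
  rev_d <- drop_analysis(list(model = s2, baseline = s1))
  expect_equal(rev_d$delta, -d$delta)
  s3 <- baseline_norm_association(
    make_norm_table(terms, cbind(fear = rnorm(60))),
    make_ratings_table(terms, y), shared_variance = "none")
  expect_error(drop_analysis(list(s1, s3)), "different norm set")
})

test_that("shared variance from joint norms tracks the planted signal", {
  set.seed(46)
  n <- 200
  y <- rnorm(n); terms <- paste0("t", 1:n)
  m <- cbind(valence = y + rnorm(n, sd = 0.5),
             fear = y + rnorm(n, sd = 0.7),
             frequency = rnorm(n))
  cfg <- cv_config(outer_folds = 5, repeats = 2, inner_folds = 5, seed = 46)
  rep <- baseline_norm_association(make_norm_table(terms, m),
                                   make_ratings_table(terms, y), cfg,
                                   shared_variance = "cv")
  # population R^2 of y ~ (valence, fear) is about 0.87
  expect_gt(rep$shared_variance, 0.6)
  expect_lte(rep$shared_variance, 1)
  rep2 <- baseline_norm_association(make_norm_table(terms, m),
                                    make_ratings_table(terms, y), cfg,
                                    shared_variance = "in_sample")
  expect_gt(rep2$shared_variance, rep$shared_variance - 0.1)
})
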
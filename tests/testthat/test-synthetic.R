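test_that("noise calibration follows the closed-form ceiling relation", {
  w <- make_world(n_words = 100, k_latent = 1, seed = 1,
                  target_ceiling_r2 = 0.8, risk_weights = 1)
  # signal variance 1, ceiling 0.8 -> noise variance 0.25
  expect_equal(w$noise_sd_risk^2, 0.25)
  expect_error(make_world(100, 2, 1, target_ceiling_r2 = 1), "inside")
  expect_error(make_world(100, 2, 1, target_ceiling_r2 = 0), "inside")
})

test_that("worlds and all samplers are deterministic under a fixed seed", {
  a <- make_world(80, 4, seed = 7)
  b <- make_world(80, 4, seed = 7)
  expect_identical(a, b)
  expect_identical(sample_ratings(a, seed = 2), sample_ratings(b, seed = 2))
  expect_identical(sample_norms(a, seed = 3), sample_norms(b, seed = 3))
  expect_identical(sample_associations(a, 30, 40, 0.2, seed = 4),
                   sample_associations(b, 30, 40, 0.2, seed = 4))
  expect_identical(sample_corpus(a, 20, 5, seed = 5),
                   sample_corpus(b, 20, 5, seed = 5))
})

test_that("near-zero noise makes risk means an affine function of the latent projection", {
  w <- make_world(120, 3, seed = 9, target_ceiling_r2 = 1 - 1e-12)
  rat <- sample_ratings(w)
  proj <- drop(w$latent_vectors %*% w$risk_weights)
  expect_gt(abs(cor(rat$risk_mean, proj)), 0.9999999)
})

test_that("sampled tables respect their scale bounds and validators", {
  w <- make_world(300, 6, seed = 10)
  rat <- sample_ratings(w)
  items <- attr(rat, "psychometric_items")
  expect_length(items, 9)
  expect_true(all(rat$risk_mean >= -100 & rat$risk_mean <= 100))
  for (it in items) expect_true(all(rat[[it]] >= 1 & rat[[it]] <= 7))
  # clipping affects well under 1% of values
  at_bound <- mean(rat$risk_mean %in% c(-100, 100))
  expect_lt(at_bound, 0.01)
  # generated tables round-trip through the package readers
  rp <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(rat), rp, row.names = FALSE)
  expect_s3_class(read_ratings(rp), "ratings_table")
  np <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(sample_norms(w)), np, row.names = FALSE)
  expect_s3_class(read_norms(np), "norm_table")
  ap <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(sample_associations(w, 40, 50, 0.2)), ap,
                   row.names = FALSE)
  expect_s3_class(read_associations(ap, "long_triple"), "association_table")
  hp <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(sample_corpus(w, 25, 6)), hp,
                   row.names = FALSE)
  expect_s3_class(read_headlines(hp), "headline_corpus")
})

test_that("temperature limits behave as argmax and uniform responding", {
  w <- make_world(60, 3, seed = 11)
  expect_error(sample_associations(w, 5, 10, temperature = 0), "positive")
  # near-zero temperature: all mass on the nearest cosine neighbour
  cold <- sample_associations(w, 5, 50, temperature = 1e-4, seed = 2)
  Zn <- w$latent_vectors / sqrt(rowSums(w$latent_vectors^2))
  sims <- Zn %*% t(Zn); diag(sims) <- -Inf
  for (cue in unique(cold$cue)) {
    i <- match(cue, w$words)
    nn <- w$words[which.max(sims[i, ])]
    d <- cold[cold$cue == cue, ]
    expect_equal(d$response, nn)
    expect_equal(d$count, 50L)
  }
  # very high temperature: responses uniform within chi-squared tolerance
  hot <- sample_associations(w, 1, 5900, temperature = 1e6, seed = 3)
  counts <- rep(0, 59)
  idx <- match(hot$response, setdiff(w$words, hot$cue[1]))
  counts[idx] <- hot$count
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 1e-3)
})

test_that("affect norms share the planted risk dimension, others do not", {
  w <- make_world(1000, 8, seed = 12)
  rat <- sample_ratings(w)
  nt <- sample_norms(w)
  groups <- attr(nt, "norm_groups")
  rs <- sapply(names(groups), function(nm) abs(cor(rat$risk_mean, nt[[nm]])))
  aff <- mean(rs[groups == "affect"])
  other <- mean(rs[groups != "affect"])
  expect_gte(aff - other, 0.3)
})

test_that("corpus generation concentrates risky words in risky topics", {
  w <- make_world(400, 5, seed = 13)
  corp <- sample_corpus(w, n_docs = 100, words_per_doc = 10)
  risky <- attr(corp, "risky_topic")
  risk <- setNames(drop(w$latent_vectors %*% w$risk_weights), w$words)
  mean_doc_risk <- sapply(tokenize(corp$title),
                          function(tt) mean(risk[tt], na.rm = TRUE))
  expect_gt(mean(mean_doc_risk[risky]), mean(mean_doc_risk[!risky]))
})
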
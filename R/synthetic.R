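canonical_psych_items <- function() {
  c("voluntariness", "immediacy", "knowledge_exposed", "knowledge_science",
    "controllability", "novelty", "catastrophic_potential", "dread",
    "fatality")
}

#' Create a synthetic semantic world
#'
#' Generates a latent semantic space in which risk ratings, psychometric
#' items and word norms are noisy linear functions of shared latent word
#' vectors — the statistical structure the analysis pipeline assumes. The
#' risk noise level is calibrated in closed form so that the population
#' R-squared of the best linear predictor of risk from the latent features
#' equals \code{target_ceiling_r2}: noise variance = signal variance x
#' (1 - R2) / R2.
#'
#' By default affect norms load on the risk-weight direction (so they
#' correlate with risk ratings and with each other) while frequency and
#' concreteness norms load on directions orthogonal to it; custom
#' \code{norm_weights} can plant any loading pattern.
#'
#' @param n_words vocabulary size (>= 50).
#' @param k_latent latent dimensionality (1..50).
#' @param seed integer seed; worlds are reproducible from it.
#' @param target_ceiling_r2 population R-squared ceiling in (0, 1).
#' @param risk_weights optional k_latent-vector overriding the random draw.
#' @param norm_weights optional named list (norm name -> k_latent-vector)
#'   overriding the default loading pattern.
#' @return object of class \code{"synthetic_world"}.
#' @export
make_world <- function(n_words = 1000, k_latent = 10, seed = 1,
                       target_ceiling_r2 = 0.8, risk_weights = NULL,
                       norm_weights = NULL) {
  stopifnot(n_words >= 50, k_latent >= 1, k_latent <= 50)
  if (!(target_ceiling_r2 > 0 && target_ceiling_r2 < 1))
    stop("target_ceiling_r2 must lie strictly inside (0, 1)")
  set.seed(seed)
  words <- sprintf("w%05d", seq_len(n_words))
  Z <- matrix(stats::rnorm(n_words * k_latent), n_words, k_latent,
              dimnames = list(words, NULL))
  w <- risk_weights %||% stats::rnorm(k_latent)
  stopifnot(length(w) == k_latent)
  signal_var <- sum(w^2)
  noise_var <- signal_var * (1 - target_ceiling_r2) / target_ceiling_r2
  u <- w / sqrt(sum(w^2))
  # psychometric items: shared risk direction plus an idiosyncratic one
  P <- matrix(NA_real_, 9, k_latent,
              dimnames = list(canonical_psych_items(), NULL))
  for (j in seq_len(9)) {
    e <- stats::rnorm(k_latent)
    e <- e - sum(e * u) * u
    if (sqrt(sum(e^2)) > 0) e <- e / sqrt(sum(e^2))
    P[j, ] <- (u + 0.6 * e) * sqrt(signal_var)
  }
  psych_noise_sd <- sqrt(rowSums(P^2) *
                           (1 - target_ceiling_r2) / target_ceiling_r2)
  if (is.null(norm_weights)) {
    gmap <- norm_group_map()
    norm_weights <- lapply(names(gmap), function(nm) {
      e <- stats::rnorm(k_latent)
      e <- e - sum(e * u) * u
      e <- e / sqrt(sum(e^2))
      if (gmap[nm] == "affect") (u + 0.4 * e) * sqrt(signal_var)
      else e * sqrt(signal_var)
    })
    names(norm_weights) <- names(gmap)
  }
  norm_noise_sd <- vapply(norm_weights, function(wn)
    sqrt(sum(wn^2) * (1 - target_ceiling_r2) / target_ceiling_r2),
    numeric(1))
  structure(list(n_words = n_words, k_latent = k_latent, seed = seed,
                 words = words, latent_vectors = Z, risk_weights = w,
                 psychometric_weights = P, norm_weights = norm_weights,
                 noise_sd_risk = sqrt(noise_var),
                 noise_sd_psych = psych_noise_sd,
                 noise_sd_norms = norm_noise_sd,
                 target_ceiling_r2 = target_ceiling_r2),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world:", x$n_words, "words,", x$k_latent,
      "latent dimensions, ceiling R^2 =", x$target_ceiling_r2, "\n")
  invisible(x)
}

# affine map of a zero-mean variable onto [center - half, center + half];
# the slope puts 3.29 population SDs at the bound so clipping affects
# ~0.1% of draws, keeping the linear ceiling calculation valid
scale_to_range <- function(raw, pop_sd, center, half) {
  pmin(center + half, pmax(center - half, center + raw * half / (3.29 * pop_sd)))
}

#' Sample risk and psychometric ratings from a world
#'
#' Risk means are latent projections plus calibrated Gaussian noise, mapped
#' affinely onto [-100, 100]; the nine psychometric item means likewise onto
#' [1, 7]. The affine maps leave fewer than 1\% of values at the bounds.
#'
#' @param world a \code{\link{make_world}} object.
#' @param seed integer seed for the rating noise.
#' @return a \code{ratings_table} over all words of the world.
#' @export
sample_ratings <- function(world, seed = world$seed + 1) {
  stopifnot(inherits(world, "synthetic_world"))
  set.seed(seed)
  Z <- world$latent_vectors
  n <- world$n_words
  raw <- drop(Z %*% world$risk_weights) +
    stats::rnorm(n, sd = world$noise_sd_risk)
  pop_sd <- sqrt(sum(world$risk_weights^2) + world$noise_sd_risk^2)
  out <- data.frame(risk_term = world$words,
                    risk_mean = scale_to_range(raw, pop_sd, 0, 100),
                    stringsAsFactors = FALSE)
  P <- world$psychometric_weights
  for (j in seq_len(nrow(P))) {
    raw_j <- drop(Z %*% P[j, ]) + stats::rnorm(n, sd = world$noise_sd_psych[j])
    sd_j <- sqrt(sum(P[j, ]^2) + world$noise_sd_psych[j]^2)
    out[[rownames(P)[j]]] <- scale_to_range(raw_j, sd_j, 4, 3)
  }
  attr(out, "psychometric_items") <- rownames(P)
  class(out) <- c("ratings_table", "data.frame")
  out
}

#' Sample word norms from a world
#'
#' Each norm is a noisy linear function of the latent vectors under the
#' world's loading pattern, carrying the canonical affect / concreteness /
#' frequency group structure.
#'
#' @param world a \code{\link{make_world}} object.
#' @param seed integer seed for the norm noise.
#' @return a \code{norm_table} over all words of the world.
#' @export
sample_norms <- function(world, seed = world$seed + 2) {
  stopifnot(inherits(world, "synthetic_world"))
  set.seed(seed)
  Z <- world$latent_vectors
  out <- data.frame(token = world$words, stringsAsFactors = FALSE)
  for (nm in names(world$norm_weights)) {
    out[[nm]] <- drop(Z %*% world$norm_weights[[nm]]) +
      stats::rnorm(world$n_words, sd = world$noise_sd_norms[[nm]])
  }
  attr(out, "norm_groups") <- norm_group_map()[names(world$norm_weights)]
  class(out) <- c("norm_table", "data.frame")
  out
}

#' Sample a free-association table from a world
#'
#' For each cue, responses are drawn from a softmax over the cosine
#' similarity between latent word vectors divided by \code{temperature}
#' (the cue itself is excluded); counts are aggregated over draws. Low
#' temperatures concentrate responses on nearest semantic neighbours, the
#' infinite-temperature limit is uniform.
#'
#' @param world a \code{\link{make_world}} object.
#' @param n_cues number of cue words (the first \code{n_cues} words).
#' @param responses_per_cue association responses drawn per cue; the default
#'   300 emulates a large association study (about 100 participants giving
#'   three responses each per cue).
#' @param temperature softmax temperature (> 0); the default 0.1 yields
#'   association-norm-like concentration, with the modal response taking
#'   a few percent of the mass.
#' @param seed integer seed for the response draws.
#' @return an \code{association_table}.
#' @export
sample_associations <- function(world, n_cues = world$n_words,
                                responses_per_cue = 300,
                                temperature = 0.1,
                                seed = world$seed + 3) {
  stopifnot(inherits(world, "synthetic_world"), n_cues <= world$n_words)
  if (temperature <= 0) stop("temperature must be positive")
  set.seed(seed)
  Z <- world$latent_vectors
  Zn <- Z / sqrt(rowSums(Z^2))
  recs <- vector("list", n_cues)
  for (i in seq_len(n_cues)) {
    sims <- drop(Zn %*% Zn[i, ])
    sims[i] <- -Inf
    logits <- sims / temperature
    p <- exp(logits - max(logits[is.finite(logits)]))
    p[i] <- 0
    p <- p / sum(p)
    cnt <- drop(stats::rmultinom(1, responses_per_cue, p))
    nz <- which(cnt > 0)
    recs[[i]] <- data.frame(cue = world$words[i],
                            response = world$words[nz],
                            count = cnt[nz], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, recs)
  tab <- tab[order(tab$cue, tab$response), ]
  rownames(tab) <- NULL
  tab$count <- as.integer(tab$count)
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' Sample a headline corpus from a world
#'
#' Generates documents whose words are drawn with probability increasing in
#' true riskiness for a "risky topic" half of the corpus and uniformly for
#' the rest, so predicted-riskiness scoring has recoverable structure.
#'
#' @param world a \code{\link{make_world}} object.
#' @param n_docs number of documents.
#' @param words_per_doc words per title.
#' @param seed integer seed.
#' @param risk_concentration softmax sharpness of the risky-topic word
#'   distribution (in units of population risk SD).
#' @return a \code{headline_corpus}.
#' @export
sample_corpus <- function(world, n_docs = 200, words_per_doc = 8,
                          seed = world$seed + 4, risk_concentration = 2) {
  stopifnot(inherits(world, "synthetic_world"), n_docs >= 1,
            words_per_doc >= 1)
  set.seed(seed)
  risk <- drop(world$latent_vectors %*% world$risk_weights)
  zrisk <- (risk - mean(risk)) / stats::sd(risk)
  p_risky <- exp(risk_concentration * zrisk)
  p_risky <- p_risky / sum(p_risky)
  risky <- seq_len(n_docs) <= n_docs / 2
  titles <- vapply(seq_len(n_docs), function(i) {
    p <- if (risky[i]) p_risky else NULL
    paste(sample(world$words, words_per_doc, replace = TRUE, prob = p),
          collapse = " ")
  }, character(1))
  out <- data.frame(
    title = titles,
    publication_date = as.character(seq(as.Date("2020-01-01"),
                                        by = "day",
                                        length.out = n_docs)),
    guid = sprintf("doc%05d", seq_len(n_docs)),
    link = sprintf("https://example.org/%05d", seq_len(n_docs)),
    description = titles,
    stringsAsFactors = FALSE)
  attr(out, "risky_topic") <- risky
  class(out) <- c("headline_corpus", "data.frame")
  out
}
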
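# shared fixture builders; everything is generated in code at test time

write_csv_fixture <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  path
}

random_embedding <- function(n_tokens, dim, seed = 1, prefix = "tok") {
  set.seed(seed)
  embedding(sprintf("%s%03d", prefix, seq_len(n_tokens)),
            matrix(rnorm(n_tokens * dim), n_tokens, dim))
}

# a norm_table built directly from a matrix of norm columns
make_norm_table <- function(tokens, norm_mat) {
  df <- data.frame(token = tokens, norm_mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  attr(df, "norm_groups") <- norm_group_map()[colnames(norm_mat)]
  class(df) <- c("norm_table", "data.frame")
  df
}

# a ratings_table built directly from a risk vector (items filled neutrally)
make_ratings_table <- function(terms, risk_mean) {
  df <- data.frame(risk_term = terms, risk_mean = risk_mean,
                   stringsAsFactors = FALSE)
  items <- c("voluntariness", "immediacy", "knowledge_exposed",
             "knowledge_science", "controllability", "novelty",
             "catastrophic_potential", "dread", "fatality")
  for (it in items) df[[it]] <- 4
  attr(df, "psychometric_items") <- items
  class(df) <- c("ratings_table", "data.frame")
  df
}

# independent cell-by-cell PPMI oracle (dense, direct formula)
ppmi_oracle <- function(M) {
  M <- as.matrix(M)
  N <- sum(M)
  out <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  rs <- rowSums(M); cs <- colSums(M)
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    if (M[i, j] > 0) {
      pmi <- log((M[i, j] / N) / ((rs[i] / N) * (cs[j] / N)))
      out[i, j] <- max(0, pmi)
    }
  }
  out
}

mean_column_sd_for_test <- function(m) mean(apply(m, 2, sd))

psych_block_from_ratings <- function(ratings) {
  items <- attr(ratings, "psychometric_items")
  feature_block("psychometric", "psychometric",
                as.matrix(ratings[items]), ratings$risk_term)
}
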
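#' Tokenize a document
#'
#' Lowercases, replaces every punctuation run with whitespace, and splits on
#' whitespace. Digits are retained as tokens.
#'
#' @param x character vector of documents.
#' @return for a single document a character vector of tokens; for several,
#'   a list of token vectors.
#' @export
tokenize <- function(x) {
  toks <- lapply(x, function(doc) {
    doc <- tolower(doc)
    doc <- gsub("[^[:alnum:]]+", " ", doc)
    out <- strsplit(trimws(doc), "\\s+")[[1]]
    out[nzchar(out)]
  })
  if (length(x) == 1) toks[[1]] else toks
}

corpus_tokens <- function(corpus) {
  stopifnot(inherits(corpus, "headline_corpus") || is.character(corpus))
  docs <- if (is.character(corpus)) corpus else corpus$title
  lapply(docs, function(d) tokenize(d))
}

#' Vocabulary coverage of a corpus
#'
#' For each document (headline title), counts the number of distinct
#' vocabulary words it contains (type counts: a repeated word counts once)
#' and reports the proportion of documents containing at least 1, 2 and 3
#' vocabulary words.
#'
#' @param corpus a \code{headline_corpus} (titles are tokenized) or a
#'   character vector of documents.
#' @param vocabulary character vector of scorable words; matched against
#'   lowercased tokens.
#' @return object of class \code{"coverage_report"}: \code{proportions}
#'   (named numeric at thresholds 1..3), \code{words_covered} (per-document
#'   distinct in-vocabulary word counts), \code{n_documents}.
#' @export
coverage <- function(corpus, vocabulary) {
  toks <- corpus_tokens(corpus)
  if (!length(toks)) stop("empty corpus")
  vocab <- unique(tolower(vocabulary))
  covered <- vapply(toks, function(tt) length(intersect(tt, vocab)),
                    integer(1))
  props <- vapply(1:3, function(k) mean(covered >= k), numeric(1))
  structure(list(proportions = stats::setNames(props,
                                               c("at_least_1", "at_least_2",
                                                 "at_least_3")),
                 words_covered = covered, n_documents = length(toks)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Coverage over", x$n_documents, "documents\n")
  cat(sprintf("  >=1 word: %.1f%%  >=2: %.1f%%  >=3: %.1f%%\n",
              100 * x$proportions[1], 100 * x$proportions[2],
              100 * x$proportions[3]))
  invisible(x)
}

#' Predicted riskiness of documents
#'
#' Scores each document by the mean predicted riskiness of its scorable
#' tokens and rescales the document means affinely across the corpus onto
#' [-100, 100] (min to -100, max to 100; if all means coincide, all scores
#' are 0). Documents with no scorable token are flagged unscored.
#'
#' @param corpus a \code{headline_corpus} or character vector.
#' @param word_scores named numeric vector: token -> predicted riskiness
#'   (names are lowercased for matching).
#' @return object of class \code{"riskiness_scores"}: data.frame with
#'   \code{guid}, \code{mean_riskiness}, \code{scaled}, \code{n_covered},
#'   \code{scored}.
#' @export
score_documents <- function(corpus, word_scores) {
  toks <- corpus_tokens(corpus)
  names(word_scores) <- tolower(names(word_scores))
  means <- vapply(toks, function(tt) {
    s <- word_scores[tt[tt %in% names(word_scores)]]
    if (!length(s)) NA_real_ else mean(s)
  }, numeric(1))
  ncov <- vapply(toks, function(tt) sum(tt %in% names(word_scores)),
                 integer(1))
  if (all(is.na(means))) stop("no document contains a scorable word")
  rng <- range(means, na.rm = TRUE)
  scaled <- if (diff(rng) == 0) ifelse(is.na(means), NA_real_, 0)
            else -100 + 200 * (means - rng[1]) / diff(rng)
  guid <- if (is.character(corpus)) as.character(seq_along(toks))
          else corpus$guid
  out <- data.frame(guid = guid, mean_riskiness = means, scaled = scaled,
                    n_covered = ncov, scored = !is.na(means),
                    stringsAsFactors = FALSE)
  class(out) <- c("riskiness_scores", "data.frame")
  out
}

#' Term-frequency / inverse-document-frequency matrix
#'
#' Builds the document-by-token matrix with tf the raw within-document count
#' and idf = log(N / df) (natural log; a token present in every document
#' gets a zero column). This is the input expected by 2-D projection
#' algorithms (e.g. UMAP), which are injected rather than bundled: any
#' function mapping a matrix to 2-D coordinates can consume the result.
#'
#' @param corpus a \code{headline_corpus} or character vector.
#' @return sparse \code{\link[Matrix]{dgCMatrix-class}}, documents x tokens,
#'   token columns sorted.
#' @export
tfidf_matrix <- function(corpus) {
  toks <- corpus_tokens(corpus)
  if (!length(toks)) stop("empty corpus")
  vocab <- sort(unique(unlist(toks)))
  N <- length(toks)
  triples <- do.call(rbind, lapply(seq_along(toks), function(i) {
    if (!length(toks[[i]])) return(NULL)
    tab <- table(toks[[i]])
    cbind(i = i, j = match(names(tab), vocab), x = as.numeric(tab))
  }))
  if (is.null(triples))
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(N, length(vocab)),
                                dimnames = list(NULL, vocab)))
  tf <- Matrix::sparseMatrix(i = triples[, "i"], j = triples[, "j"],
                             x = triples[, "x"], dims = c(N, length(vocab)),
                             dimnames = list(NULL, vocab))
  df <- Matrix::colSums(tf > 0)
  idf <- log(N / df)
  out <- tf %*% Matrix::Diagonal(x = idf)
  dimnames(out) <- dimnames(tf)
  methods::as(out, "CsparseMatrix")
}

#' Predict riskiness for arbitrary vocabulary words
#'
#' Generalizes a fitted risk model beyond the rated terms: applies the
#' model to the embedding vectors of the requested tokens. Tokens outside
#' the embedding vocabulary are skipped.
#'
#' @param model a \code{\link{risk_enet}} fitted on a single embedding block
#'   (or any design matrix with the embedding's dimensionality).
#' @param emb the \code{\link{embedding}} supplying the vectors.
#' @param tokens tokens to score; default the whole vocabulary.
#' @param scale_factor optional scalar multiplying the embedding vectors
#'   before prediction (use the groupwise scaling factor applied at
#'   training time).
#' @return named numeric vector of predicted riskiness, one entry per
#'   in-vocabulary token.
#' @export
predict_word_scores <- function(model, emb, tokens = emb$tokens,
                                scale_factor = 1) {
  stopifnot(inherits(model, "risk_enet"), inherits(emb, "embedding"))
  tokens <- intersect(tokens, emb$tokens)
  if (!length(tokens)) stop("no token found in the embedding vocabulary")
  x <- emb$vectors[tokens, , drop = FALSE] * scale_factor
  stats::setNames(predict(model, x), tokens)
}
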
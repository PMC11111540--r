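#' Construct a feature block
#'
#' A feature block is a terms-by-dimensions matrix from one source (an
#' embedding or the psychometric items), carried with its name so ensembles
#' can record column spans.
#'
#' @param name block label, e.g. "psychometric" or "swow".
#' @param source one of "embedding", "psychometric".
#' @param matrix numeric matrix, one row per term; finite values.
#' @param terms term labels; duplicate-free, length \code{nrow(matrix)}.
#' @return object of class \code{"feature_block"}.
#' @export
feature_block <- function(name, source = c("embedding", "psychometric"),
                          matrix, terms) {
  source <- match.arg(source)
  matrix <- as.matrix(matrix)
  if (anyDuplicated(terms)) stop("duplicate terms in feature block")
  if (length(terms) != nrow(matrix))
    stop("terms length does not match matrix rows")
  if (!all(is.finite(matrix))) stop("feature block contains non-finite values")
  rownames(matrix) <- terms
  structure(list(name = name, source = source, matrix = matrix,
                 terms = as.character(terms)),
            class = "feature_block")
}

#' Resolve risk terms in an embedding
#'
#' Builds a feature block for a set of risk terms (single words or
#' space-separated bigrams). Bigram handling is controlled by
#' \code{bigram_policy}:
#' \describe{
#'   \item{\code{mean_of_words}}{average the vectors of the constituent words
#'     that are in the vocabulary; a term is dropped only if none of its
#'     words are found.}
#'   \item{\code{phrase_then_mean}}{use the stored vector for the full phrase
#'     token if present, otherwise fall back to \code{mean_of_words}.}
#'   \item{\code{strict}}{drop any term with at least one out-of-vocabulary
#'     word (reproduces vocabulary-intersection behaviour).}
#' }
#'
#' @param emb an \code{\link{embedding}}.
#' @param terms character vector of risk terms.
#' @param bigram_policy see above; default \code{"mean_of_words"}.
#' @param name block name; defaults to "embedding".
#' @return a \code{\link{feature_block}} with one row per resolvable term.
#' @export
lookup_terms <- function(emb, terms,
                         bigram_policy = c("mean_of_words",
                                           "phrase_then_mean", "strict"),
                         name = "embedding") {
  stopifnot(inherits(emb, "embedding"), length(terms) > 0)
  bigram_policy <- match.arg(bigram_policy)
  vocab <- emb$tokens
  resolve <- function(term) {
    if (bigram_policy == "phrase_then_mean" && term %in% vocab)
      return(emb$vectors[term, ])
    words <- strsplit(term, "\\s+")[[1]]
    present <- words %in% vocab
    if (bigram_policy == "strict") {
      if (!all(present)) return(NULL)
    } else {
      if (!any(present)) return(NULL)
    }
    vs <- emb$vectors[words[present], , drop = FALSE]
    colMeans(vs)
  }
  rows <- lapply(terms, resolve)
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("no terms resolvable in the embedding vocabulary")
  feature_block(name, "embedding", do.call(rbind, rows[ok]), terms[ok])
}

# mean of the column standard deviations (sample, n-1 denominator)
mean_column_sd <- function(m) mean(apply(m, 2, stats::sd))

#' Groupwise scaling of feature blocks
#'
#' Rescales each block by a single scalar so that its mean column standard
#' deviation equals that of the reference block (typically the psychometric
#' block). Columns are deliberately not standardized individually: within a
#' block the relative scale of dimensions is preserved, which matters for
#' SVD-based embeddings whose variance is concentrated in leading dimensions.
#' The reference itself is never rescaled.
#'
#' @param blocks list of \code{\link{feature_block}}s sharing the reference's
#'   term set and order.
#' @param reference the \code{\link{feature_block}} whose mean column SD is
#'   the target.
#' @return list of scaled feature blocks (same order as \code{blocks}).
#' @export
groupwise_scale <- function(blocks, reference) {
  stopifnot(inherits(reference, "feature_block"))
  if (inherits(blocks, "feature_block")) blocks <- list(blocks)
  ref_msd <- mean_column_sd(reference$matrix)
  if (ref_msd == 0) stop("reference block has zero mean column SD")
  lapply(blocks, function(b) {
    stopifnot(inherits(b, "feature_block"))
    if (!identical(b$terms, reference$terms))
      stop("block '", b$name, "' terms differ from the reference")
    msd <- mean_column_sd(b$matrix)
    if (msd == 0) stop("block '", b$name, "' has zero variance in all columns")
    b$matrix <- b$matrix * (ref_msd / msd)
    b
  })
}

#' Concatenate feature blocks into an ensemble matrix
#'
#' Horizontally concatenates blocks over a common term set, recording where
#' each block's columns sit so they can be sliced back out.
#'
#' @param blocks list of \code{\link{feature_block}}s; all must contain
#'   exactly the terms of the first block (rows are aligned to its order).
#' @return object of class \code{"ensemble_matrix"}: fields \code{terms},
#'   \code{matrix} and \code{block_spans} (named list of column index
#'   vectors).
#' @export
concat_blocks <- function(blocks) {
  if (inherits(blocks, "feature_block")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1)
  terms <- blocks[[1]]$terms
  for (b in blocks) {
    extra <- setdiff(b$terms, terms)
    missing <- setdiff(terms, b$terms)
    if (length(extra) || length(missing))
      stop("term mismatch in block '", b$name, "': missing [",
           paste(utils::head(missing, 5), collapse = ", "), "], extra [",
           paste(utils::head(extra, 5), collapse = ", "), "]")
  }
  mats <- lapply(blocks, function(b) b$matrix[terms, , drop = FALSE])
  widths <- vapply(mats, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  spans <- Map(function(s, e) s:e, starts, ends)
  names(spans) <- vapply(blocks, function(b) b$name, character(1))
  m <- do.call(cbind, mats)
  colnames(m) <- unlist(Map(function(nm, w) paste0(nm, "_", seq_len(w)),
                            names(spans), widths))
  structure(list(terms = terms, matrix = m, block_spans = spans),
            class = "ensemble_matrix")
}

#' @export
print.ensemble_matrix <- function(x, ...) {
  cat("Ensemble matrix:", length(x$terms), "terms x", ncol(x$matrix),
      "columns\n  blocks:",
      paste(sprintf("%s (%d)", names(x$block_spans),
                    lengths(x$block_spans)), collapse = ", "), "\n")
  invisible(x)
}

#' Slice a block back out of an ensemble matrix
#'
#' @param ens an \code{ensemble_matrix}.
#' @param name block name.
#' @return the block's numeric matrix.
#' @export
ensemble_block <- function(ens, name) {
  stopifnot(inherits(ens, "ensemble_matrix"))
  if (!name %in% names(ens$block_spans))
    stop("no block named '", name, "'")
  ens$matrix[, ens$block_spans[[name]], drop = FALSE]
}
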
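#' Construct an embedding
#'
#' An embedding maps tokens to k-dimensional real vectors. Rows of
#' \code{vectors} are tokens, columns are dimensions.
#'
#' @param tokens character vector, duplicate-free.
#' @param vectors numeric matrix with \code{length(tokens)} rows; all finite.
#' @return an object of class \code{"embedding"}.
#' @export
embedding <- function(tokens, vectors) {
  tokens <- as.character(tokens)
  vectors <- as.matrix(vectors)
  if (length(tokens) != nrow(vectors))
    stop("number of tokens does not match number of vector rows")
  if (anyDuplicated(tokens))
    stop("duplicate tokens in embedding: ",
         paste(unique(tokens[duplicated(tokens)]), collapse = ", "))
  if (!all(is.finite(vectors)))
    stop("embedding vectors must be finite")
  rownames(vectors) <- tokens
  structure(list(tokens = tokens, vectors = vectors, dim = ncol(vectors)),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("Embedding:", length(x$tokens), "tokens x", x$dim, "dimensions\n")
  invisible(x)
}

#' @export
dim.embedding <- function(x) dim(x$vectors)

#' Look up token vectors
#'
#' @param emb an \code{embedding}.
#' @param tokens tokens to retrieve; must all be present.
#' @return numeric matrix of vectors, one row per token.
#' @export
embedding_vectors <- function(emb, tokens) {
  stopifnot(inherits(emb, "embedding"))
  missing <- setdiff(tokens, emb$tokens)
  if (length(missing))
    stop("tokens not in embedding vocabulary: ",
         paste(utils::head(missing, 5), collapse = ", "))
  emb$vectors[tokens, , drop = FALSE]
}
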
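#' Build the cue-response count matrix
#'
#' Arranges aggregated free-association counts into a sparse cue-by-response
#' matrix M, keeping only responses whose total count across all cues is
#' strictly greater than \code{min_response_freq}. All cues are retained as
#' rows.
#'
#' @param table an \code{association_table} from
#'   \code{\link{read_associations}} (or any data.frame with cue, response,
#'   count columns).
#' @param min_response_freq responses with total count \code{<=} this value
#'   are dropped. Default 5, the conventional cutoff for association norms.
#' @return a sparse \code{\link[Matrix]{dgCMatrix-class}} with cue rownames
#'   and response colnames.
#' @export
build_cue_response_matrix <- function(table, min_response_freq = 5) {
  stopifnot(is.data.frame(table), nrow(table) > 0, min_response_freq >= 1)
  if (any(table$count < 0)) stop("negative counts are invalid")
  cues <- sort(unique(table$cue))
  totals <- tapply(table$count, table$response, sum)
  keep <- names(totals)[totals > min_response_freq]
  if (!length(keep))
    stop("all responses filtered out at min_response_freq = ",
         min_response_freq)
  responses <- sort(keep)
  sel <- table$response %in% responses
  M <- Matrix::sparseMatrix(
    i = match(table$cue[sel], cues),
    j = match(table$response[sel], responses),
    x = as.numeric(table$count[sel]),
    dims = c(length(cues), length(responses)),
    dimnames = list(cues, responses))
  methods::as(M, "CsparseMatrix")
}

#' Positive pointwise mutual information transform
#'
#' Computes M' from a count matrix M:
#' \deqn{M'_{cr} = \max\!\big(0,\ \log \frac{n_{cr}\, N}{n_{c\cdot}\, n_{\cdot r}}\big)}
#' with \eqn{N} the total count, \eqn{n_{c\cdot}} row sums and
#' \eqn{n_{\cdot r}} column sums. Natural logarithm. Cells with zero joint
#' count map to 0 without evaluating the log, so sparsity is preserved.
#'
#' @param M count matrix (sparse or dense), nonnegative.
#' @return sparse matrix of the same shape and dimnames, entries >= 0.
#' @export
ppmi_transform <- function(M) {
  M <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (any(M@x < 0)) stop("negative count in matrix")
  N <- sum(M)
  if (N <= 0) stop("total count must be positive")
  rs <- Matrix::rowSums(M)
  cs <- Matrix::colSums(M)
  T <- methods::as(M, "TsparseMatrix")
  pmi <- log(T@x * N / (rs[T@i + 1L] * cs[T@j + 1L]))
  pos <- pmi > 0
  out <- Matrix::sparseMatrix(i = T@i[pos] + 1L, j = T@j[pos] + 1L,
                              x = pmi[pos], dims = dim(M),
                              dimnames = dimnames(M))
  methods::as(out, "CsparseMatrix")
}

#' Embed cues by truncated SVD
#'
#' Computes the rank-k truncated singular value decomposition
#' \eqn{M' \approx U \Sigma V^*} and returns the row embedding \eqn{U\Sigma}
#' (the right singular vectors are discarded). Singular values are in
#' descending order. The sign of each singular-vector pair is fixed so that
#' the largest-magnitude entry of each left singular vector is positive,
#' making the output deterministic across linear-algebra backends.
#'
#' @param Mp PPMI (or any real) matrix with cue rownames.
#' @param k embedding dimensionality; must satisfy
#'   \code{k <= min(nrow(Mp), ncol(Mp))}.
#' @return an \code{\link{embedding}} over the row labels of \code{Mp}.
#' @export
svd_embed <- function(Mp, k) {
  stopifnot(k >= 1)
  if (k > min(dim(Mp)))
    stop("k = ", k, " exceeds min(dim) = ", min(dim(Mp)))
  A <- as.matrix(Mp)
  s <- svd(A, nu = k, nv = 0)
  U <- s$u
  for (j in seq_len(k)) {
    sgn <- sign(U[which.max(abs(U[, j])), j])
    if (sgn < 0) U[, j] <- -U[, j]
  }
  vectors <- U %*% diag(s$d[seq_len(k)], k, k)
  tokens <- rownames(A) %||% paste0("row", seq_len(nrow(A)))
  embedding(tokens, vectors)
}

#' Train a free-association embedding
#'
#' Convenience wrapper running the three-step training procedure: count
#' matrix construction, PPMI transform, truncated SVD.
#'
#' @param table an \code{association_table}.
#' @param k embedding dimensionality.
#' @param min_response_freq response-frequency cutoff passed to
#'   \code{\link{build_cue_response_matrix}}.
#' @return an \code{\link{embedding}} over the cues.
#' @export
train_association_embedding <- function(table, k, min_response_freq = 5) {
  M <- build_cue_response_matrix(table, min_response_freq)
  svd_embed(ppmi_transform(M), k)
}
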
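#' Read a free-association table
#'
#' Reads free-association data into an aggregated long table of
#' (cue, response, count) records. Two dialects are supported:
#' \describe{
#'   \item{\code{long_triple}}{columns \code{cue}, \code{response},
#'     \code{count}; repeated (cue, response) pairs are summed.}
#'   \item{\code{swow_wide}}{participant-level rows with a \code{cue} column
#'     and response columns \code{R1}, \code{R2}, \code{R3}; each non-missing
#'     response contributes a count of 1. Missing responses may be encoded as
#'     empty cells or any of the sentinel strings in \code{missing_values}.}
#' }
#'
#' @param path path to a CSV (or TSV, see \code{sep}) file with a header row.
#' @param dialect input schema, \code{"long_triple"} or \code{"swow_wide"}.
#' @param lowercase lowercase all tokens (see \code{\link{normalize_token}}).
#' @param sep field separator, default comma.
#' @param missing_values strings treated as a missing response in
#'   \code{swow_wide} files.
#' @return a \code{data.frame} of class \code{"association_table"} with
#'   columns \code{cue}, \code{response}, \code{count}, ordered by
#'   (cue, response), one row per distinct pair.
#' @export
read_associations <- function(path,
                              dialect = c("long_triple", "swow_wide"),
                              lowercase = FALSE, sep = ",",
                              missing_values = c("", "NA", "—",
                                                 "No more responses",
                                                 "Unknown word")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", na.strings = NULL,
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (dialect == "long_triple") {
    need <- c("cue", "response", "count")
    if (!all(need %in% names(df)))
      stop("long_triple file must have columns cue, response, count")
    cue <- normalize_token(df$cue, lowercase)
    response <- normalize_token(df$response, lowercase)
    count <- suppressWarnings(as.numeric(df$count))
    bad <- which(is.na(count) | count < 1 | count != round(count) |
                   !nzchar(cue) | !nzchar(response))
    if (length(bad))
      stop("malformed row at line ", bad[1] + 1L,
           " (counts must be positive integers, tokens nonempty)")
    tab <- data.frame(cue = cue, response = response,
                      count = as.integer(count), stringsAsFactors = FALSE)
  } else {
    if (!"cue" %in% names(df))
      stop("swow_wide file must have a cue column")
    rcols <- intersect(c("R1", "R2", "R3"), names(df))
    if (!length(rcols))
      stop("swow_wide file must have response columns R1..R3")
    cue <- normalize_token(df$cue, lowercase)
    if (any(!nzchar(cue)))
      stop("malformed row at line ", which(!nzchar(cue))[1] + 1L,
           " (empty cue)")
    recs <- lapply(rcols, function(cl) {
      resp <- normalize_token(df[[cl]], lowercase)
      keep <- !(resp %in% missing_values) & nzchar(resp)
      data.frame(cue = cue[keep], response = resp[keep],
                 count = rep(1L, sum(keep)), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, recs)
    if (!nrow(tab)) stop("no responses found in swow_wide file")
  }
  agg <- stats::aggregate(count ~ cue + response, data = tab, FUN = sum)
  agg <- agg[order(agg$cue, agg$response), c("cue", "response", "count")]
  rownames(agg) <- NULL
  agg$count <- as.integer(agg$count)
  class(agg) <- c("association_table", "data.frame")
  agg
}

#' Read word vectors in word2vec text format
#'
#' The word2vec text format is a header line \code{"n_tokens dim"} followed by
#' one line per token: the token and \code{dim} whitespace-separated floats.
#'
#' @param path path to the vector file.
#' @param lowercase lowercase tokens on read.
#' @return an \code{\link{embedding}}, token order preserved.
#' @export
read_word_vectors <- function(path, lowercase = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2) stop("invalid word2vec header: ", lines[1])
  n <- as.integer(header[1]); k <- as.integer(header[2])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != n)
    stop("header declares ", n, " tokens but file has ", length(body), " rows")
  parts <- strsplit(body, "\\s+")
  tokens <- character(n)
  vecs <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) != k + 1L)
      stop("dimension mismatch at row ", i, ": expected ", k,
           " values, got ", length(p) - 1L)
    tokens[i] <- p[1]
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v)) stop("non-numeric vector entry at row ", i)
    vecs[i, ] <- v
  }
  tokens <- normalize_token(tokens, lowercase)
  if (anyDuplicated(tokens))
    stop("duplicate token in vector file: ",
         tokens[duplicated(tokens)][1])
  embedding(tokens, vecs)
}

#' Write word vectors in word2vec text format
#'
#' @param emb an \code{\link{embedding}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_word_vectors <- function(emb, path) {
  stopifnot(inherits(emb, "embedding"))
  if (!length(emb$tokens)) stop("cannot write an empty embedding")
  if (any(grepl("\\s", emb$tokens)))
    stop("tokens containing whitespace cannot be represented in ",
         "word2vec text format")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(length(emb$tokens), emb$dim), con)
  rows <- apply(emb$vectors, 1, function(v)
    paste(formatC(v, digits = 10, format = "g"), collapse = " "))
  writeLines(paste(emb$tokens, rows), con)
  invisible(path)
}

# canonical norm-name -> group assignment
norm_group_map <- function() {
  c(valence = "affect", dominance = "affect", arousal = "affect",
    fear = "affect", anger = "affect", sadness = "affect",
    disgust = "affect", joy = "affect", trust = "affect",
    surprise = "affect", anticipation = "affect",
    age_of_acquisition = "frequency", familiarity = "frequency",
    frequency = "frequency",
    concreteness = "concreteness", imageability = "concreteness")
}

#' Read a risk-ratings table
#'
#' Expects a CSV with a \code{risk_term} column, a \code{risk_mean} column on
#' the -100..100 scale, and nine psychometric item columns on the 1..7 scale.
#' Optional columns \code{reliability_risk} and \code{reliability_psych}
#' (constant within file) are attached as attributes.
#'
#' @param path path to the CSV file.
#' @param lowercase lowercase risk terms on read.
#' @return validated \code{data.frame} of class \code{"ratings_table"} with
#'   attribute \code{psychometric_items} naming the nine item columns.
#' @export
read_ratings <- function(path, lowercase = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("risk_term", "risk_mean") %in% names(df)))
    stop("ratings file must have columns risk_term and risk_mean")
  df$risk_term <- normalize_token(df$risk_term, lowercase)
  rel_cols <- intersect(c("reliability_risk", "reliability_psych"), names(df))
  items <- setdiff(names(df), c("risk_term", "risk_mean", rel_cols))
  if (length(items) != 9)
    stop("expected 9 psychometric item columns, found ", length(items))
  if (anyDuplicated(df$risk_term))
    stop("duplicate risk_term: ", df$risk_term[duplicated(df$risk_term)][1])
  bad <- which(df$risk_mean < -100 | df$risk_mean > 100 | is.na(df$risk_mean))
  if (length(bad))
    stop("risk_mean out of [-100, 100] for term '", df$risk_term[bad[1]], "'")
  for (it in items) {
    v <- df[[it]]
    bad <- which(is.na(v) | v < 1 | v > 7)
    if (length(bad))
      stop("psychometric item '", it, "' out of [1, 7] for term '",
           df$risk_term[bad[1]], "'")
  }
  out <- df[c("risk_term", "risk_mean", items)]
  attr(out, "psychometric_items") <- items
  for (rc in rel_cols) {
    r <- unique(df[[rc]])
    if (length(r) != 1 || r < 0 || r > 1)
      stop(rc, " must be a single value in [0, 1]")
    attr(out, rc) <- r
  }
  class(out) <- c("ratings_table", "data.frame")
  out
}

#' Read a word-norm table
#'
#' Expects a wide CSV with a \code{token} column and one column per norm.
#' Norm names must belong to the canonical groups: affect (valence, dominance,
#' arousal, fear, anger, sadness, disgust, joy, trust, surprise,
#' anticipation), frequency (age_of_acquisition, familiarity, frequency) and
#' concreteness (concreteness, imageability).
#'
#' @param path path to the CSV file.
#' @param lowercase lowercase tokens on read.
#' @return \code{data.frame} of class \code{"norm_table"} with attribute
#'   \code{norm_groups}: a named character vector mapping norm name to group.
#' @export
read_norms <- function(path, lowercase = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!"token" %in% names(df)) stop("norms file must have a token column")
  df$token <- normalize_token(df$token, lowercase)
  if (anyDuplicated(df$token))
    stop("duplicate token in norms: ", df$token[duplicated(df$token)][1])
  norms <- setdiff(names(df), "token")
  gmap <- norm_group_map()
  unknown <- setdiff(norms, names(gmap))
  if (length(unknown))
    stop("unknown norm group for norm(s): ", paste(unknown, collapse = ", "))
  for (nm in norms)
    if (!is.numeric(df[[nm]])) stop("norm column '", nm, "' is not numeric")
  attr(df, "norm_groups") <- gmap[norms]
  class(df) <- c("norm_table", "data.frame")
  df
}

#' Read a headline corpus
#'
#' Expects a CSV with columns \code{title}, \code{publication_date},
#' \code{guid}, \code{link}, \code{description}.
#'
#' @param path path to the CSV file.
#' @return \code{data.frame} of class \code{"headline_corpus"}.
#' @export
read_headlines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  need <- c("title", "publication_date", "guid", "link", "description")
  if (!all(need %in% names(df)))
    stop("headline file must have columns: ", paste(need, collapse = ", "))
  if (any(!nzchar(trimws(df$title))))
    stop("empty title at row ", which(!nzchar(trimws(df$title)))[1])
  if (anyDuplicated(df$guid))
    stop("duplicate guid: ", df$guid[duplicated(df$guid)][1])
  out <- df[need]
  class(out) <- c("headline_corpus", "data.frame")
  out
}
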
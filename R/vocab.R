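#' Machine votes by embedding similarity
#'
#' Scores each candidate word by its cosine similarity to a set of seed
#' risks under one embedding and marks it positive when its score exceeds a
#' threshold chosen to match the rate of positive human responses: the
#' threshold is the empirical (1 - \code{human_positive_rate}) quantile of
#' the candidate scores, so the machine positive rate equals the human rate
#' up to ties.
#'
#' @param candidates candidate tokens; must be in the embedding vocabulary.
#' @param emb an \code{\link{embedding}} (one voter; call once per voting
#'   embedding).
#' @param seed_risks tokens of previously studied risks, resolvable in the
#'   embedding.
#' @param human_positive_rate target positive rate in (0, 1).
#' @param similarity_stat aggregate similarity across seeds by \code{"max"}
#'   (default: a word close to any known risk is risk-like) or
#'   \code{"mean"}.
#' @return logical vector, one vote per candidate.
#' @export
machine_vote <- function(candidates, emb, seed_risks, human_positive_rate,
                         similarity_stat = c("max", "mean")) {
  similarity_stat <- match.arg(similarity_stat)
  stopifnot(length(seed_risks) > 0,
            human_positive_rate > 0, human_positive_rate < 1)
  C <- embedding_vectors(emb, candidates)
  S <- embedding_vectors(emb, seed_risks)
  Cn <- C / sqrt(rowSums(C^2))
  Sn <- S / sqrt(rowSums(S^2))
  sims <- Cn %*% t(Sn)
  score <- if (similarity_stat == "max") apply(sims, 1, max)
           else rowMeans(sims)
  thr <- stats::quantile(score, 1 - human_positive_rate, type = 1,
                         names = FALSE)
  stats::setNames(score > thr, candidates)
}

#' Combine human and machine votes
#'
#' A candidate is accepted when it received at least two human votes, or one
#' human vote together with at least two of three machine votes.
#'
#' @param human_votes nonnegative integer vector.
#' @param machine_votes nonnegative integer vector (recycled).
#' @return logical vector of acceptance decisions.
#' @export
combine_votes <- function(human_votes, machine_votes) {
  stopifnot(all(human_votes >= 0), all(machine_votes >= 0))
  human_votes >= 2 | (human_votes == 1 & machine_votes >= 2)
}

#' Final filters for the curated risk list
#'
#' Applies the three closing filters to accepted candidates: drop words of
#' very low frequency, keep exactly one word per lemma (the most frequent;
#' ties broken lexicographically), and drop sensitive words.
#'
#' @param accepted data.frame with columns \code{word}, \code{frequency},
#'   \code{lemma} and optionally a logical \code{sensitive} column.
#' @param min_frequency words with \code{frequency < min_frequency} are
#'   dropped (no universal default exists; supply a corpus-appropriate
#'   cutoff).
#' @param sensitive_list additional words to drop.
#' @return character vector of surviving words, sorted.
#' @export
filter_candidates <- function(accepted, min_frequency,
                              sensitive_list = character()) {
  stopifnot(is.data.frame(accepted),
            all(c("word", "frequency", "lemma") %in% names(accepted)))
  df <- accepted[accepted$frequency >= min_frequency, , drop = FALSE]
  if (nrow(df)) {
    # one survivor per lemma: highest frequency, then lexicographic
    df <- df[order(df$lemma, -df$frequency, df$word), , drop = FALSE]
    df <- df[!duplicated(df$lemma), , drop = FALSE]
  }
  if ("sensitive" %in% names(df))
    df <- df[!isTRUE_vec(df$sensitive), , drop = FALSE]
  out <- setdiff(df$word, sensitive_list)
  sort(out)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
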
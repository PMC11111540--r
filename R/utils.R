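#' Normalize tokens
#'
#' Applies the package-wide token policy used by all readers and matchers:
#' Unicode NFC normalization and stripping of surrounding whitespace.
#' Lowercasing is off by default because free-association cues are
#' case-preserving; when requested it is applied uniformly.
#'
#' @param x character vector of tokens.
#' @param lowercase logical; lowercase after normalization.
#' @return character vector of normalized tokens.
#' @export
normalize_token <- function(x, lowercase = FALSE) {
  x <- stringi::stri_trans_nfc(enc2utf8(as.character(x)))
  x <- trimws(x)
  if (lowercase) x <- tolower(x)
  x
}

# coefficient of determination on a held-out set, 1 - SS_res / SS_tot with
# SS_tot around the held-out mean (the scikit-learn r2_score convention)
r_squared <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("R^2 undefined: observed values are constant")
  1 - sum((obs - pred)^2) / ss_tot
}

# derive a stream of 32-bit seeds from one master seed, deterministically
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
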
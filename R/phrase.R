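#' Normalize a phrase for matching
#'
#' Phrases are compared case-insensitively with surrounding punctuation
#' removed, so equivalence-set members and story text meet on equal footing.
#' Lowercases, splits on whitespace, and strips leading/trailing punctuation
#' from each token. Intra-word hyphens are kept, and any token beginning with
#' "http" is kept verbatim (URL fragments are matched by the boilerplate
#' filter downstream).
#'
#' @param x Character vector of phrases.
#' @return Character vector of normalized phrases (single-space separated,
#'   lowercase tokens). Phrases that normalize to nothing become `""`.
#' @export
#' @examples
#' normalize_phrase("Picked Up,")
normalize_phrase <- function(x) {
  vapply(x, function(p) paste(tokenize(p), collapse = " "), character(1),
         USE.NAMES = FALSE)
}

#' Tokenize text into matching tokens
#'
#' The tokenization used throughout extraction: lowercase, whitespace split,
#' leading/trailing punctuation stripped per token (intra-word hyphens and
#' apostrophes survive), "http..."-prefixed tokens kept intact, empty tokens
#' dropped.
#'
#' @param x A single character string.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' tokenize("Five poachers were arrested on June 10, 2019.")
tokenize <- function(x) {
  if (length(x) != 1L || is.na(x)) {
    stop("`x` must be a single non-NA string", call. = FALSE)
  }
  toks <- strsplit(tolower(x), "\\s+")[[1]]
  keep_raw <- startsWith(toks, "http")
  stripped <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", toks)
  toks <- ifelse(keep_raw, toks, stripped)
  toks[nzchar(toks)]
}

# n-grams of a token vector as space-joined strings; assumes 1 <= n <= length
ngrams <- function(tokens, n) {
  k <- length(tokens) - n + 1L
  vapply(seq_len(k), function(i) paste(tokens[i:(i + n - 1L)], collapse = " "),
         character(1))
}
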
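#' Configuration for the phrasal overlap similarity measure
#'
#' @param ngram_common_threshold Two n-grams count as "common" when
#'   1 minus their normalized Levenshtein distance exceeds this value
#'   (default 0.99, i.e. near-exact agreement for short strings).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ngram_common_threshold = 0.99) {
  stopifnot(is.numeric(ngram_common_threshold),
            ngram_common_threshold > 0, ngram_common_threshold <= 1)
  structure(list(ngram_common_threshold = ngram_common_threshold),
            class = "sim_config")
}

#' Levenshtein edit distance
#'
#' Standard unit-cost insert/delete/substitute edit distance between two
#' strings, computed character-wise.
#'
#' @param a,b Character strings (vectors are recycled element-wise).
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein("kitten", "sitting")  # 3
levenshtein <- function(a, b) {
  d <- utils::adist(a, b, costs = 1L)
  if (length(a) == length(b)) as.integer(diag(d)) else as.integer(d)
}

#' Normalized character-level string similarity
#'
#' `1 - levenshtein(a, b) / max(nchar(a), nchar(b))`: 1 for identical strings,
#' 0 for strings sharing no aligned characters. This is the "1.0 minus the
#' Levenshtein distance" quantity used both for the n-gram commonality test
#' and the single-word special case of [phrase_similarity()].
#'
#' @param a,b Character strings.
#' @return Numeric in `[0, 1]`.
#' @export
normalized_similarity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (any(la == 0L & lb == 0L)) {
    stop("normalized similarity is undefined for two empty strings",
         call. = FALSE)
  }
  1 - levenshtein(a, b) / pmax(la, lb)
}

#' Count n-grams common to two phrases
#'
#' An n-gram of the shorter phrase is common when some not-yet-consumed
#' n-gram of the longer phrase has normalized character similarity above
#' `cfg$ngram_common_threshold`. Longer-phrase n-grams are consumed greedily
#' left-to-right, one-to-one, so a repeated word cannot inflate the count and
#' the result never exceeds `length(ph1) - n + 1`.
#'
#' @param ph1,ph2 Phrases as strings or token vectors; `ph1` must be the
#'   shorter (or equal) phrase.
#' @param n n-gram length, `1 <= n <= length of ph1`.
#' @param cfg A [sim_config()].
#' @return Integer count `m_n`.
#' @export
common_ngram_count <- function(ph1, ph2, n, cfg = sim_config()) {
  t1 <- if (length(ph1) > 1L) ph1 else tokenize(ph1)
  t2 <- if (length(ph2) > 1L) ph2 else tokenize(ph2)
  if (n < 1L || n > length(t1)) {
    stop("`n` must lie in [1, length(ph1)]", call. = FALSE)
  }
  g1 <- ngrams(t1, n)
  if (n > length(t2)) return(0L)
  g2 <- ngrams(t2, n)
  sim <- 1 - utils::adist(g1, g2) / outer(nchar(g1), nchar(g2), pmax)
  consumed <- rep(FALSE, length(g2))
  m <- 0L
  for (i in seq_along(g1)) {
    hit <- which(!consumed & sim[i, ] > cfg$ngram_common_threshold)
    if (length(hit)) {
      consumed[hit[1L]] <- TRUE
      m <- m + 1L
    }
  }
  m
}

#' Phrasal overlap similarity between two phrases
#'
#' The modified Phrasal Overlap Measure used to match story phrases against
#' equivalence-set members:
#' \deqn{SIM(ph_1, ph_2) = \frac{N}{|ph_2|}\tanh\left[\frac{1}{s}\sum_{n=1}^{N} m_n n^2\right]}
#' where the arguments are ordered so that \eqn{N = |ph_1| \le |ph_2|},
#' \eqn{m_n} is the number of common n-grams (see [common_ngram_count()]),
#' and \eqn{s = \sum_{n=1}^{N} (N - n + 1) = N(N+1)/2} counts the n-gram pair
#' formations that start at the same position in each phrase. When both
#' phrases are single words the score is instead the character-level
#' [normalized_similarity()]. Squared n-gram length rewards longer contiguous
#' agreement; the `N/|ph2|` prefactor penalizes absorbing a short phrase into
#' a much longer one.
#'
#' An identical pair scores 1 for single words and
#' \eqn{\ge \tanh(2) \approx 0.964} for all longer phrases, which is why the
#' extraction verb/object gates sit at 0.95.
#'
#' @param ph1,ph2 Phrases as strings (tokenized internally) or token vectors.
#' @param cfg A [sim_config()].
#' @return A `sim_breakdown` list: `score`, `N`, `len2`, `s`, `m` (named
#'   vector of `m_n`), `prefactor`, `single_word`.
#' @seealso [phrase_sim()] for the bare score.
#' @export
#' @examples
#' phrase_similarity("picked up", "picked up")$score  # tanh(2)
phrase_similarity <- function(ph1, ph2, cfg = sim_config()) {
  t1 <- if (length(ph1) > 1L) ph1 else tokenize(ph1)
  t2 <- if (length(ph2) > 1L) ph2 else tokenize(ph2)
  if (!length(t1) || !length(t2)) {
    stop("both phrases must contain at least one token", call. = FALSE)
  }
  if (length(t1) > length(t2)) { tmp <- t1; t1 <- t2; t2 <- tmp }
  N <- length(t1); L2 <- length(t2)
  if (N == 1L && L2 == 1L) {
    score <- normalized_similarity(t1, t2)
    return(structure(list(score = max(0, score), N = 1L, len2 = 1L, s = 1L,
                          m = c(`1` = as.integer(score > cfg$ngram_common_threshold)),
                          prefactor = 1, single_word = TRUE),
                     class = "sim_breakdown"))
  }
  m <- vapply(seq_len(N), function(n) common_ngram_count(t1, t2, n, cfg),
              integer(1))
  names(m) <- seq_len(N)
  s <- N * (N + 1L) / 2
  overlap <- sum(m * seq_len(N)^2) / s
  structure(list(score = (N / L2) * tanh(overlap), N = N, len2 = L2,
                 s = as.integer(s), m = m, prefactor = N / L2,
                 single_word = FALSE),
            class = "sim_breakdown")
}

#' @export
print.sim_breakdown <- function(x, ...) {
  cat(sprintf("SIM = %.4f  (N = %d, |ph2| = %d, s = %d, prefactor = %.3f)\n",
              x$score, x$N, x$len2, x$s, x$prefactor))
  if (!x$single_word) {
    cat("  m_n:", paste(sprintf("m_%s=%d", names(x$m), x$m), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Bare phrasal similarity score
#'
#' Convenience wrapper around [phrase_similarity()] returning just the score;
#' `ph2` may be a character vector of candidate phrases, in which case the
#' score against each is returned.
#'
#' @inheritParams phrase_similarity
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
phrase_sim <- function(ph1, ph2, cfg = sim_config()) {
  vapply(ph2, function(p) phrase_similarity(ph1, p, cfg)$score, numeric(1),
         USE.NAMES = FALSE)
}
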
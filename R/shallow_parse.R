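PREPOSITIONS <- c("of", "in", "on", "at", "to", "from", "with", "by", "for",
                  "against", "into", "during", "over", "under", "inside")
CONJUNCTIONS <- c("and", "or", "but", "that", "which", "who", "because",
                  "while", "when")
AUXILIARIES <- c("be", "am", "is", "are", "was", "were", "been", "being",
                 "have", "has", "had", "do", "does", "did", "will", "would")

#' Find taxonomy verbs in a sentence
#'
#' Scans the sentence for maximal non-overlapping token spans whose phrase
#' matches a member of the verb lexicon with similarity above `gate`.
#' Longer spans win over shorter ones at the same position (so a phrasal
#' verb like "picked up" is returned whole, not as "picked"), auxiliaries
#' (forms of be/have/do) are never returned alone, and a passive participle
#' is returned without its auxiliary.
#'
#' @param sentence A sentence string or token vector.
#' @param verb_lexicon Character vector of verb phrases — in practice the
#'   union of all taxonomy verb equivalence-set members.
#' @param gate Similarity gate (default 0.95).
#' @param cfg A [sim_config()].
#' @return Tibble with columns `verb` (matched span, space-joined), `start`,
#'   `end` (1-based token indices), `lexeme` (best lexicon member), `score`.
#' @export
extract_verbs <- function(sentence, verb_lexicon, gate = 0.95,
                          cfg = sim_config()) {
  toks <- if (length(sentence) > 1L) sentence else tokenize(sentence)
  out <- tibble::tibble(verb = character(), start = integer(),
                        end = integer(), lexeme = character(),
                        score = numeric())
  if (!length(toks) || !length(verb_lexicon)) return(out)
  lex_tok <- strsplit(verb_lexicon, " ", fixed = TRUE)
  max_m <- max(lengths(lex_tok))
  taken <- rep(FALSE, length(toks))
  for (m in seq(min(max_m, length(toks)), 1L)) {
    members <- verb_lexicon[lengths(lex_tok) == m]
    if (!length(members)) next
    for (i in seq_len(length(toks) - m + 1L)) {
      span_idx <- i:(i + m - 1L)
      if (any(taken[span_idx])) next
      span <- toks[span_idx]
      if (m == 1L && span %in% AUXILIARIES) next
      scores <- phrase_sim(span, members, cfg)
      best <- which.max(scores)
      if (scores[best] > gate) {
        taken[span_idx] <- TRUE
        out <- dplyr::bind_rows(out, tibble::tibble(
          verb = paste(span, collapse = " "), start = i,
          end = i + m - 1L, lexeme = members[best], score = scores[best]))
      }
    }
  }
  dplyr::arrange(out, .data$start)
}

is_boundary <- function(tok, verb_positions = integer()) {
  tok %in% PREPOSITIONS | tok %in% CONJUNCTIONS
}

#' Extract the direct-object chunk governed by a verb
#'
#' For an active verb, the contiguous noun-phrase chunk immediately after it
#' (unknown words are treated as nominal material; the chunk stops at a
#' preposition, conjunction, auxiliary or another extracted verb). For a
#' passive construction — the verb span immediately preceded by a form of
#' *be* — the chunk immediately preceding the auxiliary is returned instead,
#' mirroring the treatment of "Five poachers were arrested" as verb
#' "arrested" with object "five poachers".
#'
#' @param sentence Sentence string or token vector.
#' @param verb_start,verb_end 1-based token indices of the verb span (as
#'   returned by [extract_verbs()]).
#' @param verb_spans Optional integer vector of all tokens covered by
#'   extracted verbs (used as chunk boundaries).
#' @return The object phrase as a string, or `NA_character_` when no chunk
#'   exists.
#' @export
extract_object_phrase <- function(sentence, verb_start, verb_end = verb_start,
                                  verb_spans = integer()) {
  toks <- if (length(sentence) > 1L) sentence else tokenize(sentence)
  stopifnot(verb_start >= 1L, verb_end <= length(toks))
  be_forms <- c("be", "am", "is", "are", "was", "were", "been", "being")
  passive <- verb_start > 1L && toks[verb_start - 1L] %in% be_forms

  stop_at <- function(idx) {
    is_boundary(toks[idx]) || toks[idx] %in% AUXILIARIES || idx %in% verb_spans
  }
  if (passive) {
    j <- verb_start - 2L
    chunk <- integer()
    while (j >= 1L && !stop_at(j)) { chunk <- c(j, chunk); j <- j - 1L }
  } else {
    j <- verb_end + 1L
    chunk <- integer()
    while (j <= length(toks) && !stop_at(j)) { chunk <- c(chunk, j); j <- j + 1L }
  }
  if (!length(chunk)) return(NA_character_)
  paste(toks[chunk], collapse = " ")
}

#' Extract prepositional-phrase candidates from a sentence
#'
#' Each candidate starts at a preposition from a fixed closed-class list. Two
#' spans are emitted per start when they differ: the maximal span (up to the
#' next conjunction, extracted verb, or sentence end) and the span truncated
#' at the next preposition. Emitting both keeps short taxonomy members like
#' "to prison" and longer ones like "to predict poaching plots in advance"
#' both reachable. Candidates may overlap each other and the object chunk;
#' sentence order is preserved.
#'
#' @param sentence Sentence string or token vector.
#' @param verb_spans Optional integer vector of token indices covered by
#'   extracted verbs (treated as boundaries).
#' @return Tibble with columns `phrase`, `start`, `end`.
#' @export
extract_prep_phrases <- function(sentence, verb_spans = integer()) {
  toks <- if (length(sentence) > 1L) sentence else tokenize(sentence)
  out <- tibble::tibble(phrase = character(), start = integer(),
                        end = integer())
  starts <- which(toks %in% PREPOSITIONS)
  for (p in starts) {
    j <- p + 1L
    first_prep <- NA_integer_
    while (j <= length(toks) && !(toks[j] %in% CONJUNCTIONS) &&
           !(j %in% verb_spans)) {
      if (is.na(first_prep) && toks[j] %in% PREPOSITIONS) first_prep <- j
      j <- j + 1L
    }
    long_end <- j - 1L
    if (long_end <= p) next  # bare preposition, no phrase
    ends <- unique(c(if (!is.na(first_prep) && first_prep - 1L > p)
                       first_prep - 1L,
                     long_end))
    for (e in ends) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        phrase = paste(toks[p:e], collapse = " "), start = p, end = e))
    }
  }
  dplyr::arrange(out, .data$start, .data$end)
}

#' Shallow-parse a sentence into verbs, object candidates, and prep phrases
#'
#' Runs [extract_verbs()], then [extract_object_phrase()] per verb and
#' [extract_prep_phrases()] once, returning everything the entity-extraction
#' cascade needs. Deterministic: the same sentence and lexicon always yield
#' the same parse. All returned spans are contiguous token slices of the
#' sentence.
#'
#' @param sentence Sentence string.
#' @param verb_lexicon Verb lexicon (see [extract_verbs()]).
#' @param gate Verb similarity gate.
#' @param cfg A [sim_config()].
#' @return A list of class `sentence_parse`: `tokens`, `verbs` (tibble with
#'   added `object` column), `preps` (tibble).
#' @export
parse_sentence <- function(sentence, verb_lexicon, gate = 0.95,
                           cfg = sim_config()) {
  toks <- tokenize(sentence)
  verbs <- extract_verbs(toks, verb_lexicon, gate, cfg)
  verb_spans <- unlist(purrr::map2(verbs$start, verbs$end, seq),
                       use.names = FALSE)
  if (is.null(verb_spans)) verb_spans <- integer()
  verbs$object <- purrr::map2_chr(
    verbs$start, verbs$end,
    function(s, e) extract_object_phrase(toks, s, e,
                                         verb_spans = setdiff(verb_spans, s:e)))
  preps <- extract_prep_phrases(toks, verb_spans = verb_spans)
  structure(list(sentence = paste(toks, collapse = " "), tokens = toks,
                 verbs = verbs, preps = preps),
            class = "sentence_parse")
}

#' @export
print.sentence_parse <- function(x, ...) {
  cat("<sentence_parse> ", x$sentence, "\n", sep = "")
  cat("  verbs:  ", paste(x$verbs$verb, collapse = "; "), "\n")
  cat("  objects:", paste(stats::na.omit(x$verbs$object), collapse = "; "),
      "\n")
  cat("  preps:  ", paste(x$preps$phrase, collapse = "; "), "\n")
  invisible(x)
}
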
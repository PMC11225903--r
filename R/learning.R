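#' Keyword-in-context search over a story file
#'
#' The first stage of taxonomy learning: short query strings (one to four
#' words) thought to describe an action in part are located in the corpus,
#' and the surrounding usage suggests verbs, objects, and prepositional
#' phrases to add to that action's equivalence sets. Matching is
#' case-insensitive substring search per sentence; `window` context
#' sentences on each side are attached. When a taxonomy is supplied, each
#' hit sentence is shallow-parsed and its verb/object/prep candidates are
#' included as suggestions.
#'
#' @param queries Character vector; each query must have 1--4 words.
#' @param stories An `emat_story_file` tibble or story-file path.
#' @param window Context sentences either side of a hit (default 1).
#' @param taxonomy Optional `emat_taxonomy` for parse-based suggestions.
#' @param filter_cfg A [content_filter_config()] (hits are searched in the
#'   full sentence list, not just content sentences).
#' @return Tibble with columns `query`, `story_id`, `sentence_index`,
#'   `sentence`, `context`, and (with a taxonomy) `verbs`, `objects`,
#'   `preps` list-columns.
#' @export
find_phrase_contexts <- function(queries, stories, window = 1L,
                                 taxonomy = NULL,
                                 filter_cfg = content_filter_config()) {
  nw <- lengths(strsplit(trimws(queries), "\\s+"))
  if (any(nw < 1L | nw > 4L)) {
    stop("each query must contain one to four words", call. = FALSE)
  }
  if (is.character(stories) && length(stories) == 1L) {
    stories <- read_story_file(stories)
  }
  lex <- if (!is.null(taxonomy)) verb_lexicon(taxonomy)
  out <- list()
  for (s in seq_len(nrow(stories))) {
    sents <- segment_sentences(strip_html(stories$text[s]))
    if (!length(sents)) next
    low <- tolower(sents)
    for (q in queries) {
      hits <- which(grepl(tolower(q), low, fixed = TRUE))
      for (i in hits) {
        ctx <- sents[max(1L, i - window):min(length(sents), i + window)]
        row <- tibble::tibble(query = q, story_id = stories$story_id[s],
                              sentence_index = i, sentence = sents[i],
                              context = paste(ctx, collapse = " "))
        if (!is.null(taxonomy)) {
          p <- parse_sentence(sents[i], lex)
          row$verbs <- list(p$verbs$verb)
          row$objects <- list(stats::na.omit(p$verbs$object))
          row$preps <- list(p$preps$phrase)
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (!length(out)) {
    base <- tibble::tibble(query = character(), story_id = integer(),
                           sentence_index = integer(), sentence = character(),
                           context = character())
    return(base)
  }
  dplyr::bind_rows(out)
}

#' Detect learning candidates from extraction traces
#'
#' Mines the cascade traces for sentences that nearly matched: those whose
#' best prepositional similarity (before gating) lies in the band
#' `[learn_low, prep_accept)`, and those where the best direct-object
#' similarity exceeds the best prepositional similarity. Each candidate
#' carries the associated action (a SIMP or SIMD score always points at a
#' particular action) and the trigger that fired; duplicate
#' (sentence, action) pairs collapse. Sentences that were also extracted can
#' still appear — the overlap is informative, not an error.
#'
#' @param traces Trace tibble from [parse_stories()] (`$traces`) or rows
#'   from [extract_entity_from_sentence()].
#' @param cfg An [extraction_config()].
#' @return Tibble with columns `story_id`, `sentence_index`, `sentence`,
#'   `action_id`, `trigger` (`"simp_band"` or `"simd_gt_simp"`), `simp`,
#'   `simd`, `verb`, `object`, `prep` (the sentence's parsed phrases).
#' @export
detect_candidates <- function(traces, cfg = extraction_config()) {
  empty <- tibble::tibble(story_id = integer(), sentence_index = integer(),
                          sentence = character(), action_id = integer(),
                          trigger = character(), simp = numeric(),
                          simd = numeric(), verb = character(),
                          object = character(), prep = character())
  if (!nrow(traces)) return(empty)
  tr <- traces[lengths(traces$cluster) > 0, ]
  if (!nrow(tr)) return(empty)
  if (!"story_id" %in% names(tr)) tr$story_id <- NA_integer_
  if (!"sentence_index" %in% names(tr)) tr$sentence_index <- NA_integer_

  mk <- function(rows, trigger, action) {
    tibble::tibble(story_id = rows$story_id,
                   sentence_index = rows$sentence_index,
                   sentence = rows$sentence, action_id = action,
                   trigger = trigger, simp = rows$simp_raw,
                   simd = rows$simd_raw, verb = rows$verb,
                   object = rows$object_raw, prep = rows$prep_raw)
  }
  band <- tr[tr$simp_raw >= cfg$learn_low & tr$simp_raw < cfg$prep_accept &
               !is.na(tr$actionP_raw), ]
  dgtp <- tr[tr$simd_raw > tr$simp_raw & !is.na(tr$actionD_raw), ]
  out <- dplyr::bind_rows(mk(band, "simp_band", band$actionP_raw),
                          mk(dgtp, "simd_gt_simp", dgtp$actionD_raw))
  out[!duplicated(paste(out$sentence, out$action_id, out$trigger,
                        sep = "\r")), ]
}

#' Render a human-readable learning report
#'
#' For each candidate: the sentence, the associated action, the scores, and
#' two ready-to-apply suggestion blocks — arguments for
#' [add_equivalence_member()] when the sentence describes the existing
#' action, and an [add_action()] skeleton using the sentence's own
#' verb/object/prep as initial equivalence-set members when it describes a
#' new one. The human chooses; nothing is applied automatically.
#'
#' @param candidates Tibble from [detect_candidates()].
#' @param taxonomy An `emat_taxonomy` (for action labels).
#' @return A single string (the report); `cat()` it or write it to a file.
#' @export
render_candidate_report <- function(candidates, taxonomy) {
  if (!nrow(candidates)) return("")
  blocks <- vapply(seq_len(nrow(candidates)), function(i) {
    c <- candidates[i, ]
    label <- taxonomy$label[match(c$action_id, taxonomy$action_id)]
    sugg_add <- paste(
      sprintf("  add_equivalence_member(taxonomy, %d, \"verb\", \"%s\")",
              c$action_id, c$verb),
      if (!is.na(c$object))
        sprintf("  add_equivalence_member(taxonomy, %d, \"object\", \"%s\")",
                c$action_id, c$object),
      if (!is.na(c$prep))
        sprintf("  add_equivalence_member(taxonomy, %d, \"prep\", \"%s\")",
                c$action_id, c$prep),
      sep = "\n")
    sugg_new <- sprintf(
      paste0("  add_action(taxonomy, label = \"<new action label>\",\n",
             "    category = \"<category>\", verb = \"%s\",\n",
             "    object = %s, prep = %s)"),
      c$verb,
      if (is.na(c$object)) "NULL" else sprintf("\"%s\"", c$object),
      if (is.na(c$prep)) "NULL" else sprintf("\"%s\"", c$prep))
    paste0(
      sprintf("candidate %d [%s]  SIMP=%.3f SIMD=%.3f\n", i, c$trigger,
              c$simp, c$simd),
      sprintf("  sentence: %s\n", c$sentence),
      sprintf("  associated action %d: %s\n", c$action_id, label),
      "  if this is the existing action, add its phrases:\n", sugg_add, "\n",
      "  if this is a new action, start from:\n", sugg_new, "\n")
  }, character(1))
  paste(blocks, collapse = "\n")
}
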
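#' Extraction thresholds
#'
#' The cascade declares a verb or direct-object match above 0.95 — just
#' below the identity floor tanh(2) of the similarity measure — while
#' prepositional-phrase matches are declared and accepted at 0.8, and the
#' learning band collects near-misses with best prepositional similarity in
#' `[learn_low, prep_accept)`.
#'
#' @param verb_gate Verb match gate (default 0.95).
#' @param object_gate Direct-object match gate (default 0.95).
#' @param prep_gate Prepositional-phrase match gate (default 0.8).
#' @param prep_accept Acceptance threshold on SIMP (default 0.8).
#' @param learn_low Lower edge of the learning band (default 0.7).
#' @param sim A [sim_config()].
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(verb_gate = 0.95, object_gate = 0.95,
                              prep_gate = 0.8, prep_accept = 0.8,
                              learn_low = 0.7, sim = sim_config()) {
  stopifnot(learn_low > 0, learn_low <= prep_accept, prep_accept <= 1,
            verb_gate > 0, verb_gate <= 1, object_gate > 0, object_gate <= 1,
            prep_gate > 0, prep_gate <= 1)
  structure(list(verb_gate = verb_gate, object_gate = object_gate,
                 prep_gate = prep_gate, prep_accept = prep_accept,
                 learn_low = learn_low, sim = sim),
            class = "extraction_config")
}

#' Verb lexicon of a taxonomy
#'
#' Union of all verb equivalence-set members, used to spot candidate verbs
#' in sentences.
#'
#' @param taxonomy An `emat_taxonomy`.
#' @return Character vector of verb phrases.
#' @export
verb_lexicon <- function(taxonomy) {
  unique(unlist(taxonomy$verbs, use.names = FALSE))
}

#' Score a sentence verb against every action's verb set
#'
#' The first step of the extraction cascade: the verb is scored against
#' every member of every action's verb equivalence set; every action with a
#' member above the gate joins the action cluster, and the action owning the
#' single best-scoring member is the cluster's best action (ties broken by
#' lowest `action_id`).
#'
#' @param verb Verb phrase (string or token vector).
#' @param taxonomy An `emat_taxonomy`.
#' @param cfg An [extraction_config()].
#' @return List: `best_action` (id or `NA`), `best_score`, `cluster`
#'   (integer vector of action ids, possibly empty).
#' @export
build_action_cluster <- function(verb, taxonomy, cfg = extraction_config()) {
  best_action <- NA_integer_; best_score <- 0; cluster <- integer()
  ord <- order(taxonomy$action_id)
  for (i in ord) {
    members <- taxonomy$verbs[[i]]
    if (!length(members)) next
    sc <- max(phrase_sim(verb, members, cfg$sim))
    if (sc > cfg$verb_gate) {
      cluster <- c(cluster, taxonomy$action_id[i])
      if (sc > best_score) { best_score <- sc; best_action <- taxonomy$action_id[i] }
    }
  }
  list(best_action = best_action, best_score = best_score, cluster = cluster)
}

# best (action, score, member, candidate) over cluster actions for one role
best_role_match <- function(candidates, taxonomy, cluster, role_col, cfg) {
  best <- list(action = NA_integer_, score = 0, member = NA_character_,
               candidate = NA_character_)
  candidates <- candidates[!is.na(candidates) & nzchar(candidates)]
  if (!length(candidates) || !length(cluster)) return(best)
  for (id in sort(cluster)) {
    members <- taxonomy[[role_col]][[match(id, taxonomy$action_id)]]
    if (!length(members)) next
    for (cand in candidates) {
      sc <- phrase_sim(cand, members, cfg$sim)
      j <- which.max(sc)
      if (sc[j] > best$score) {
        best <- list(action = id, score = sc[j], member = members[j],
                     candidate = cand)
      }
    }
  }
  best
}

#' Run the entity-extraction cascade on one parsed sentence
#'
#' Implements the cascade: (i) find the best verb match over all verb
#' equivalence sets and form the action cluster; (ii) no verb match returns
#' nothing; (iii) SIMD and SIMP start at 0; (iv) best direct-object match
#' within the cluster above `object_gate` sets `actionD`/`SIMD`; (v) best
#' prepositional match within the cluster above `prep_gate` sets
#' `actionP`/`SIMP`; (vi) both null returns nothing; (vii) `SIMP >
#' prep_accept` returns `actionP`; (viii) `SIMD > SIMP` returns `actionD`,
#' otherwise nothing. The trace additionally records the best sub-gate
#' object/prep matches, which the learning module mines for new
#' equivalence-set members.
#'
#' @param parse A [parse_sentence()] result.
#' @param taxonomy An `emat_taxonomy`.
#' @param cfg An [extraction_config()].
#' @return A one-row tibble trace with columns `sentence`, `verb`,
#'   `verb_score`, `cluster` (list), `actionD`, `simd`, `actionP`, `simp`,
#'   `actionD_raw`, `simd_raw`, `actionP_raw`, `simp_raw`, `object`, `prep`,
#'   `accepted`, `action_id`, `rule`.
#' @export
extract_entity_from_sentence <- function(parse, taxonomy,
                                         cfg = extraction_config()) {
  trace <- tibble::tibble(
    sentence = parse$sentence, verb = NA_character_, verb_score = 0,
    cluster = list(integer()), actionD = NA_integer_, simd = 0,
    actionP = NA_integer_, simp = 0, actionD_raw = NA_integer_, simd_raw = 0,
    actionP_raw = NA_integer_, simp_raw = 0, object = NA_character_,
    prep = NA_character_, object_raw = NA_character_,
    prep_raw = NA_character_, verb_start = NA_integer_,
    accepted = FALSE, action_id = NA_integer_, rule = "no_verb")

  if (!nrow(parse$verbs)) return(trace)
  # step i: best verb over all spans and all verb sets
  best_verb <- NULL; best_cl <- list(best_score = 0)
  for (k in seq_len(nrow(parse$verbs))) {
    cl <- build_action_cluster(parse$verbs$verb[k], taxonomy, cfg)
    if (cl$best_score > best_cl$best_score) {
      best_cl <- cl; best_verb <- parse$verbs[k, ]
    }
  }
  if (!length(best_cl$cluster)) return(trace)  # step ii
  trace$verb <- best_verb$verb
  trace$verb_score <- best_cl$best_score
  trace$verb_start <- best_verb$start
  trace$cluster <- list(best_cl$cluster)

  # steps iii-v: SIMD/SIMP initialized 0; best object and prep matches in
  # cluster. Raw bests are kept even when below the gates.
  objD <- best_role_match(parse$verbs$object, taxonomy, best_cl$cluster,
                          "objects", cfg)
  prP <- best_role_match(parse$preps$phrase, taxonomy, best_cl$cluster,
                         "preps", cfg)
  trace$actionD_raw <- objD$action; trace$simd_raw <- objD$score
  trace$actionP_raw <- prP$action; trace$simp_raw <- prP$score
  trace$object_raw <- objD$candidate; trace$prep_raw <- prP$candidate
  if (objD$score > cfg$object_gate) {
    trace$actionD <- objD$action; trace$simd <- objD$score
    trace$object <- objD$candidate
  }
  if (prP$score > cfg$prep_gate) {
    trace$actionP <- prP$action; trace$simp <- prP$score
    trace$prep <- prP$candidate
  }

  if (is.na(trace$actionD) && is.na(trace$actionP)) {  # step vi
    trace$rule <- "no_dp"
    return(trace)
  }
  if (trace$simp > cfg$prep_accept) {                  # step vii
    trace$accepted <- TRUE; trace$action_id <- trace$actionP
    trace$rule <- "prep_accept"
  } else if (trace$simd > trace$simp) {                # step viii
    trace$accepted <- TRUE; trace$action_id <- trace$actionD
    trace$rule <- "object_over_prep"
  } else {
    trace$rule <- "rejected"
  }
  trace
}

MONTHS <- c("january", "february", "march", "april", "may", "june", "july",
            "august", "september", "october", "november", "december")

extract_date <- function(text) {
  low <- tolower(text)
  m <- regmatches(low, regexpr(
    "content\\s*=\\s*[\"']?(\\d{4}-\\d{2}-\\d{2})", low, perl = TRUE))
  if (length(m)) {
    d <- sub(".*?(\\d{4}-\\d{2}-\\d{2}).*", "\\1", m)
    out <- suppressWarnings(as.Date(d))
    if (!is.na(out)) return(out)
  }
  mon_re <- paste(MONTHS, collapse = "|")
  pats <- c(
    sprintf("(%s)\\s+(\\d{1,2})(?:st|nd|rd|th)?\\s*,?\\s*(\\d{4})", mon_re),
    sprintf("(\\d{1,2})(?:st|nd|rd|th)?\\s+(%s)\\s*,?\\s*(\\d{4})", mon_re),
    "(\\d{4})-(\\d{2})-(\\d{2})")
  orders <- c("mdy", "dmy", "ymd")
  for (k in seq_along(pats)) {
    m <- regmatches(low, regexec(pats[k], low, perl = TRUE))[[1]]
    if (!length(m)) next
    parts <- m[-1]
    d <- switch(orders[k],
      mdy = as.Date(sprintf("%04d-%02d-%02d", as.integer(parts[3]),
                            match(parts[1], MONTHS), as.integer(parts[2]))),
      dmy = as.Date(sprintf("%04d-%02d-%02d", as.integer(parts[3]),
                            match(parts[2], MONTHS), as.integer(parts[1]))),
      ymd = suppressWarnings(as.Date(paste(parts, collapse = "-"))))
    if (!is.na(d)) return(d)
  }
  as.Date(NA)
}

# longest-match, case-insensitive occurrences of lexicon names in text
find_lexicon_hits <- function(text, lexicon) {
  out <- tibble::tibble(name = character(), start = integer(),
                        end = integer())
  if (!length(lexicon) || !nzchar(text)) return(out)
  low <- tolower(text)
  for (nm in lexicon) {
    pos <- gregexpr(tolower(nm), low, fixed = TRUE)[[1]]
    if (pos[1] == -1L) next
    out <- dplyr::bind_rows(out, tibble::tibble(
      name = nm, start = as.integer(pos),
      end = as.integer(pos) + nchar(nm) - 1L))
  }
  if (!nrow(out)) return(out)
  out <- dplyr::arrange(out, .data$start, dplyr::desc(.data$end))
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    inside <- out$start >= out$start[i] & out$end <= out$end[i] &
      seq_len(nrow(out)) != i
    keep[inside & keep] <- FALSE
  }
  out[keep, ]
}

#' Tag a story with its date, group hits, and region hits
#'
#' The date comes from an ordered battery: a `content="YYYY-MM-DD"` meta-tag
#' attribute surviving in the raw text, then "Month D, YYYY", then
#' "D Month YYYY", then bare ISO. Group and region hits are case-insensitive
#' longest-match occurrences of lexicon names, each with character position.
#' The three searches are independent, so running them sequentially or
#' concurrently gives identical results.
#'
#' @param text Tag-filtered story text (pass raw text to let the meta-tag
#'   date rule see attributes).
#' @param groups,regions Character lexicons (see [read_lexicon()]).
#' @return List: `date` (Date or `NA`), `group_hits`, `region_hits`
#'   (tibbles with `name`, `start`, `end`).
#' @export
tag_story <- function(text, groups = character(), regions = character()) {
  list(date = extract_date(text),
       group_hits = find_lexicon_hits(text, groups),
       region_hits = find_lexicon_hits(text, regions))
}

# token-level lexicon hits within one sentence
sentence_lexicon_hits <- function(tokens, lexicon) {
  out <- tibble::tibble(name = character(), start = integer(),
                        end = integer())
  for (nm in lexicon) {
    nt <- tokenize(nm)
    ln <- length(nt)
    if (!ln || ln > length(tokens)) next
    for (i in seq_len(length(tokens) - ln + 1L)) {
      if (all(tokens[i:(i + ln - 1L)] == nt)) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          name = nm, start = i, end = i + ln - 1L))
      }
    }
  }
  out
}

#' Attribute an actor and target to an extracted entity
#'
#' Actor: the nearest group hit at or before the verb in the sentence, else
#' the first group hit anywhere in the story, else the action's first
#' archetypal actor, else none. Target: the nearest group or region hit
#' after the verb in the sentence, else the first story-level region hit,
#' else none. The rule that fired is recorded as provenance.
#'
#' @param tokens Sentence token vector.
#' @param verb_start Token index of the matched verb.
#' @param groups,regions Character lexicons.
#' @param story_tags A [tag_story()] result for the whole story.
#' @param action One-row slice of the taxonomy (for archetypal actors).
#' @return List: `actor`, `actor_rule`, `target`, `target_rule`.
#' @export
assign_actor_target <- function(tokens, verb_start, groups, regions,
                                story_tags, action) {
  g_hits <- sentence_lexicon_hits(tokens, groups)
  r_hits <- sentence_lexicon_hits(tokens, regions)

  actor <- NA_character_; actor_rule <- "none"
  before <- g_hits[g_hits$start <= verb_start, ]
  if (nrow(before)) {
    actor <- before$name[which.max(before$end)]; actor_rule <- "sentence"
  } else if (nrow(story_tags$group_hits)) {
    actor <- story_tags$group_hits$name[1]; actor_rule <- "story"
  } else if (length(action$actors[[1]])) {
    actor <- action$actors[[1]][1]; actor_rule <- "archetype"
  }

  target <- NA_character_; target_rule <- "none"
  after <- dplyr::bind_rows(g_hits, r_hits)
  after <- after[after$start > verb_start, ]
  if (nrow(after)) {
    target <- after$name[which.min(after$start)]; target_rule <- "sentence"
  } else if (nrow(story_tags$region_hits)) {
    target <- story_tags$region_hits$name[1]; target_rule <- "story"
  }
  list(actor = actor, actor_rule = actor_rule,
       target = target, target_rule = target_rule)
}

#' Remove duplicate entities
#'
#' Two entities are duplicates when they agree on
#' `(action_id, story_id, date, actor, target)` — the smallest key under
#' which the same real-world event reported twice in one story collapses.
#' The first occurrence survives; the list is re-scanned until no duplicates
#' of the current entity remain, so all later copies go. Idempotent,
#' order-preserving.
#'
#' @param entities Entity tibble.
#' @return The tibble with later duplicates removed.
#' @export
deduplicate <- function(entities) {
  if (!nrow(entities)) return(entities)
  key <- paste(entities$action_id, entities$story_id,
               as.character(entities$date), entities$actor, entities$target,
               sep = "\r")
  entities[!duplicated(key), ]
}

empty_entities <- function() {
  tibble::tibble(story_id = integer(), sentence_index = integer(),
                 action_id = integer(), label = character(),
                 date = as.Date(character()), source = character(),
                 actor = character(), target = character(),
                 region = character(), verb = character(),
                 object = character(), prep = character(),
                 verb_score = numeric(), simd = numeric(), simp = numeric(),
                 rule = character(), actor_rule = character(),
                 target_rule = character())
}

#' Extract EMAT entities from a story file
#'
#' The full driver: for each story, strip HTML, keep textual-content
#' sentences, shallow-parse each sentence, run the extraction cascade, tag
#' the story with date/group/region hits, attribute actor and target, and
#' collect entities; duplicates are removed per story and then globally.
#' Stories yielding no content sentences, or neither a date nor any parsed
#' sentence, are logged as parse failures. Extraction from one story never
#' depends on another, so extraction over a concatenation of story files
#' equals the concatenation of per-file extractions (before global dedup).
#'
#' @param stories An `emat_story_file` tibble (see [read_story_file()]) or a
#'   path to a story file.
#' @param taxonomy An `emat_taxonomy`.
#' @param groups,regions Character lexicons or lexicon file paths.
#' @param cfg An [extraction_config()].
#' @param filter_cfg A [content_filter_config()].
#' @param out_entities,out_sdb,out_parsefailed,out_sample Optional output
#'   paths: the flat entity-history file (TSV), the per-story database file,
#'   the parse-failure log, and the extraction-assessment sample
#'   (see [write_assessment_sample()]).
#' @param progress Emit per-story progress to stderr.
#' @return An `emat_story_db` list: `entities` (tibble, globally deduped),
#'   `per_story` (list of per-story entity tibbles), `traces` (tibble of all
#'   cascade traces with `story_id`/`sentence_index`), `parsefailed`
#'   (tibble `story_id`, `reason`), `story_meta` (tibble `story_id`,
#'   `source`, `date`, `n_sentences`).
#' @export
parse_stories <- function(stories, taxonomy, groups = character(),
                          regions = character(),
                          cfg = extraction_config(),
                          filter_cfg = content_filter_config(),
                          out_entities = NULL, out_sdb = NULL,
                          out_parsefailed = NULL, out_sample = NULL,
                          progress = FALSE) {
  if (is.character(stories) && length(stories) == 1L) {
    stories <- read_story_file(stories)
  }
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    groups <- read_lexicon(groups)
  }
  if (is.character(regions) && length(regions) == 1L && file.exists(regions)) {
    regions <- read_lexicon(regions)
  }
  lexicon <- verb_lexicon(taxonomy)

  per_story <- list()
  traces <- list()
  failed <- tibble::tibble(story_id = integer(), reason = character())
  meta <- tibble::tibble(story_id = integer(), source = character(),
                         date = as.Date(character()), n_sentences = integer())

  for (s in seq_len(nrow(stories))) {
    sid <- stories$story_id[s]
    if (progress) message("story ", sid, "/", nrow(stories))
    raw <- stories$text[s]
    ent <- empty_entities()
    res <- tryCatch({
      src <- detect_source(raw)
      clean <- strip_html(raw)
      tags <- tag_story(raw, groups, regions)
      sents <- content_fragment(clean, filter_cfg)
      meta <- dplyr::bind_rows(meta, tibble::tibble(
        story_id = sid, source = src, date = tags$date,
        n_sentences = length(sents)))
      if (!length(sents)) {
        failed <- dplyr::bind_rows(failed, tibble::tibble(
          story_id = sid, reason = "no content sentences"))
      } else {
        any_parse <- FALSE
        for (i in seq_along(sents)) {
          parse <- parse_sentence(sents[i], lexicon, cfg$verb_gate, cfg$sim)
          if (nrow(parse$verbs)) any_parse <- TRUE
          tr <- extract_entity_from_sentence(parse, taxonomy, cfg)
          tr$story_id <- sid; tr$sentence_index <- i
          traces[[length(traces) + 1L]] <- tr
          if (tr$accepted) {
            act <- taxonomy[match(tr$action_id, taxonomy$action_id), ]
            at <- assign_actor_target(parse$tokens, tr$verb_start, groups,
                                      regions, tags, act)
            ent <- dplyr::bind_rows(ent, tibble::tibble(
              story_id = sid, sentence_index = i, action_id = tr$action_id,
              label = act$label, date = tags$date, source = src,
              actor = at$actor, target = at$target,
              region = if (nrow(tags$region_hits))
                tags$region_hits$name[1] else NA_character_,
              verb = tr$verb, object = tr$object, prep = tr$prep,
              verb_score = tr$verb_score, simd = tr$simd, simp = tr$simp,
              rule = tr$rule, actor_rule = at$actor_rule,
              target_rule = at$target_rule))
          }
        }
        if (!any_parse && is.na(tags$date)) {
          failed <- dplyr::bind_rows(failed, tibble::tibble(
            story_id = sid, reason = "no date and no sentence parse"))
        }
      }
      deduplicate(ent)
    }, error = function(e) {
      failed <<- dplyr::bind_rows(failed, tibble::tibble(
        story_id = sid, reason = paste("extraction error:",
                                       conditionMessage(e))))
      empty_entities()
    })
    per_story[[as.character(sid)]] <- res
  }

  entities <- deduplicate(dplyr::bind_rows(per_story))
  traces <- if (length(traces)) dplyr::bind_rows(traces) else
    tibble::tibble()
  db <- structure(list(entities = entities, per_story = per_story,
                       traces = traces, parsefailed = failed,
                       story_meta = meta),
                  class = "emat_story_db")

  if (!is.null(out_entities)) write_entity_history(db, out_entities)
  if (!is.null(out_sdb)) write_story_database(db, out_sdb)
  if (!is.null(out_parsefailed)) {
    writeLines(sprintf("%d\t%s", failed$story_id, failed$reason),
               out_parsefailed)
  }
  if (!is.null(out_sample)) {
    write_assessment_sample(stories, db, k = 10L, out_path = out_sample)
  }
  db
}

fmt_ent_line <- function(e) {
  sprintf("%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%.4f\t%.4f\t%.4f",
          e$story_id, e$action_id,
          ifelse(is.na(e$date), "NA", as.character(e$date)),
          ifelse(is.na(e$source), "NA", e$source),
          ifelse(is.na(e$actor), "NA", e$actor),
          ifelse(is.na(e$target), "NA", e$target),
          ifelse(is.na(e$region), "NA", e$region),
          ifelse(is.na(e$verb), "NA", e$verb),
          ifelse(is.na(e$object), "NA", e$object),
          ifelse(is.na(e$prep), "NA", e$prep),
          e$verb_score, e$simd, e$simp)
}

#' Write the flat entity-history file
#'
#' One tab-separated record per extracted entity: story id, action id, ISO
#' date, source, actor, target, region, matched verb/object/prep phrases,
#' and the three similarity scores.
#'
#' @param db An `emat_story_db`.
#' @param path Output path.
#' @return `db`, invisibly.
#' @export
write_entity_history <- function(db, path) {
  hdr <- paste("story_id", "action_id", "date", "source", "actor", "target",
               "region", "verb", "object", "prep", "verb_score", "simd",
               "simp", sep = "\t")
  lines <- if (nrow(db$entities)) fmt_ent_line(db$entities) else character()
  writeLines(c(hdr, lines), path)
  invisible(db)
}

#' Write the per-story database file
#'
#' One block per story: a `story <id> <source> <date>` header followed by
#' that story's entity records (same record format as
#' [write_entity_history()]).
#'
#' @param db An `emat_story_db`.
#' @param path Output path.
#' @return `db`, invisibly.
#' @export
write_story_database <- function(db, path) {
  lines <- character()
  for (sid in names(db$per_story)) {
    m <- db$story_meta[db$story_meta$story_id == as.integer(sid), ]
    lines <- c(lines, sprintf("story %s\t%s\t%s", sid,
                              if (nrow(m)) m$source[1] else "unknown",
                              if (nrow(m) && !is.na(m$date[1]))
                                as.character(m$date[1]) else "NA"))
    e <- db$per_story[[sid]]
    if (nrow(e)) lines <- c(lines, fmt_ent_line(e))
  }
  writeLines(lines, path)
  invisible(db)
}

#' @export
print.emat_story_db <- function(x, ...) {
  cat("<emat_story_db>\n")
  cat("  stories:      ", nrow(x$story_meta), "\n")
  cat("  entities:     ", nrow(x$entities), "\n")
  cat("  parse failed: ", nrow(x$parsefailed), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy emat_story_db
#' @export
tidy.emat_story_db <- function(x, ...) x$entities

#' @method glance emat_story_db
#' @export
glance.emat_story_db <- function(x, ...) {
  tibble::tibble(n_stories = nrow(x$story_meta),
                 n_entities = nrow(x$entities),
                 n_actions = length(unique(x$entities$action_id)),
                 n_failed = nrow(x$parsefailed),
                 n_sentences = sum(x$story_meta$n_sentences))
}
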
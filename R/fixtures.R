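# closed-class and filter vocabulary that planted content words must avoid
closed_class_words <- function() {
  cf <- content_filter_config()
  unique(c(PREPOSITIONS, CONJUNCTIONS, AUXILIARIES, cf$common_words,
           cf$irrelevant_words, MONTHS))
}

.rng_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
}

.rng_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- .rng_get()
  on.exit(.rng_set(old), add = TRUE)
  set.seed(seed)
  code
}

# deterministic pseudo-word pool: consonant-vowel syllable compounds (4 or 6
# characters), closed-class words excluded
make_vocab <- function(n, seed) {
  cons <- c("b", "d", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(cons, vow, paste0))
  two <- as.vector(outer(syll, syll, paste0))
  three <- as.vector(outer(two, syll, paste0))
  pool <- setdiff(c(two, three), closed_class_words())
  if (n > length(pool)) stop("vocabulary pool exhausted", call. = FALSE)
  with_seed(seed, sample(pool, n))
}

# taxonomy with the given number of actions per category, disjoint
# per-action vocabulary
gen_taxonomy <- function(counts, vocab_seed, confusable = FALSE) {
  stopifnot(length(counts) == 5L, all(counts >= 0L))
  n_act <- sum(counts)
  wpa <- 14L  # words per action
  vocab <- make_vocab(n_act * wpa + 40L, vocab_seed)
  actor_pool <- vocab[n_act * wpa + seq_len(40L)]
  common_preps <- intersect(PREPOSITIONS,
                            content_filter_config()$common_words)
  with_seed(vocab_seed + 1L, {
    rows <- lapply(seq_len(n_act), function(i) {
      w <- if (confusable) {
        sample(vocab[seq_len(min(3L * wpa, n_act * wpa))], wpa)
      } else {
        vocab[((i - 1L) * wpa + 1L):(i * wpa)]
      }
      list(verbs = unique(c(w[1], w[2], paste(w[3], w[4]))),
           objects = unique(c(paste(w[5], w[6]), paste(w[7], w[8], w[9]))),
           preps = unique(c(paste(sample(common_preps, 1L), w[10], w[11]),
                            paste(sample(common_preps, 1L), w[12], w[13],
                                  w[14]))),
           actor = paste(tools::toTitleCase(
             actor_pool[((i - 1L) %% 40L) + 1L]), "Authority"))
    })
    emat_taxonomy(
      action_id = seq_len(n_act),
      category = rep(emat_categories, times = counts),
      label = sprintf("synthetic action %03d", seq_len(n_act)),
      actors = lapply(rows, function(r) r$actor),
      verbs = lapply(rows, function(r) r$verbs),
      objects = lapply(rows, function(r) r$objects),
      preps = lapply(rows, function(r) r$preps)
    )
  })
}

#' Generate a toy taxonomy with disjoint controlled vocabulary
#'
#' Builds `actions_per_category` actions in each of the five categories.
#' Each action gets 2--3 members per equivalence set (including one phrasal
#' two-word verb) drawn from a pseudo-word vocabulary that is disjoint
#' across actions, so a planted sentence can only match the action it was
#' built from. Prepositional members start with a closed-class preposition
#' that is also a common word, and each action carries a two-word title-case
#' archetypal actor. Deterministic in `vocab_seed`. `confusable = TRUE`
#' instead draws action vocabularies from a shared pool, for stress-testing
#' attribution.
#'
#' @param actions_per_category Actions per category (>= 1).
#' @param vocab_seed Integer seed.
#' @param confusable Share vocabulary across actions (default `FALSE`).
#' @return An `emat_taxonomy` with `5 * actions_per_category` actions.
#' @export
generate_toy_taxonomy <- function(actions_per_category, vocab_seed,
                                  confusable = FALSE) {
  stopifnot(actions_per_category >= 1L)
  gen_taxonomy(rep(as.integer(actions_per_category), 5L), vocab_seed,
               confusable)
}

#' Synthetic stand-in for a full-scale curated taxonomy
#'
#' The curated reference taxonomy at its reported size (119
#' militaristic, 191 diplomatic, 198 economic, 92 ecosystem-directed, 37
#' ecological actions) ships as supplementary material elsewhere and is not
#' redistributed here. This generator builds a synthetic taxonomy of the
#' same shape and size — same five categories at those counts, three
#' equivalence sets per action — for exercising the readers, writers, and
#' counters at full scale. Content is pseudo-word, not curated.
#'
#' @param vocab_seed Integer seed (default 1).
#' @return An `emat_taxonomy` with 637 actions.
#' @export
synthetic_reference_taxonomy <- function(vocab_seed = 1L) {
  gen_taxonomy(c(119L, 191L, 198L, 92L, 37L), vocab_seed)
}

# single-character edit driven by pre-drawn uniforms (common random numbers:
# the same uniforms serve every perturbation rate, so a higher rate perturbs
# a superset of the words a lower rate perturbs)
perturb_word <- function(word, type_u, pos_u, char_u) {
  n <- nchar(word)
  pos <- min(n, 1L + floor(pos_u * n))
  ch <- letters[min(26L, 1L + floor(char_u * 26))]
  type <- if (type_u < 1 / 3 && n > 1L) "del" else if (type_u < 2 / 3)
    "sub" else "ins"
  switch(type,
         del = paste0(substr(word, 1, pos - 1L), substr(word, pos + 1L, n)),
         sub = paste0(substr(word, 1, pos - 1L), ch,
                      substr(word, pos + 1L, n)),
         ins = paste0(substr(word, 1, pos), ch, substr(word, pos + 1L, n)))
}

perturb_sentence <- function(sentence, rate, u) {
  words <- strsplit(sentence, " ", fixed = TRUE)[[1]]
  for (i in seq_along(words)) {
    if (u$p[i] < rate) {
      words[i] <- perturb_word(words[i], u$type[i], u$pos[i], u$char[i])
    }
  }
  paste(words, collapse = " ")
}

#' Plant one sentence describing a taxonomy action
#'
#' Builds a sentence of the shape the extraction cascade assumes —
#' `"<Actor> <verb> <object> <prep member> in the <Region> on <Month D,
#' YYYY>."` — from sampled equivalence-set members, then perturbs each word
#' independently with probability `perturbation` by one character edit
#' (substitute/insert/delete), modelling the scraping noise the 0.99 n-gram
#' commonality rule has to absorb. The trailing location/date material
#' guarantees at least three common words, so unperturbed planted sentences
#' always pass the content filter. Uses the current RNG state; wrap in a
#' seed for reproducibility.
#'
#' @param action One-row slice of an `emat_taxonomy`.
#' @param actor,region Actor group and region names (put them in the
#'   lexicons so story tagging can find them).
#' @param date A `Date`.
#' @param perturbation Per-word perturbation probability in `[0, 1]`.
#' @return List: `sentence` (string), `truth` (one-row tibble with the
#'   planted `action_id`, `verb`, `object`, `prep`, `actor`, `region`,
#'   `date`).
#' @export
plant_sentence <- function(action, actor = "Field Authority",
                           region = "Northern Plains",
                           date = as.Date("2019-06-10"), perturbation = 0) {
  stopifnot(nrow(action) == 1L, length(action$verbs[[1]]) >= 1L)
  pick <- function(set) if (length(set)) sample(set, 1L) else ""
  verb <- pick(action$verbs[[1]])
  object <- pick(action$objects[[1]])
  prep <- pick(action$preps[[1]])
  lt <- as.POSIXlt(date)
  datestr <- sprintf("%s %d, %d", tools::toTitleCase(MONTHS[lt$mon + 1L]),
                     lt$mday, lt$year + 1900L)
  core <- trimws(gsub("  +", " ", paste(actor, verb, object, prep)))
  sentence <- sprintf("%s in the %s on %s.", core, region, datestr)
  n_words <- length(strsplit(sentence, " ", fixed = TRUE)[[1]])
  u <- tibble::tibble(p = stats::runif(n_words),
                      type = stats::runif(n_words),
                      pos = stats::runif(n_words),
                      char = stats::runif(n_words))
  sentence <- perturb_sentence(sentence, perturbation, u)
  list(sentence = sentence,
       truth = tibble::tibble(action_id = action$action_id, verb = verb,
                              object = object, prep = prep, actor = actor,
                              region = region, date = date))
}

junk_sentence <- function() {
  irr <- setdiff(content_filter_config()$irrelevant_words, "http:")
  paste(c(sample(irr, sample(4:7, 1L), replace = TRUE),
          "http://tracker.example/x"), collapse = " ")
}

#' Specification for a synthetic story file
#'
#' @param n_stories Number of stories.
#' @param entities_per_story Planted action sentences per story (distinct
#'   actions within a story).
#' @param junk_sentence_rate Boilerplate-sentence insertion probability at
#'   each slot boundary, in `[0, 1]`.
#' @param word_perturbation_rate Per-word single-character-edit probability
#'   in planted sentences, in `[0, 1]`.
#' @param html_fluff Wrap each story in HTML scaffolding (head, script,
#'   style, div, paragraph tags).
#' @param seed Integer seed (mandatory; the whole fixture is a deterministic
#'   function of it).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_stories, entities_per_story,
                         junk_sentence_rate = 0.3,
                         word_perturbation_rate = 0, html_fluff = TRUE,
                         seed) {
  stopifnot(junk_sentence_rate >= 0, junk_sentence_rate <= 1,
            word_perturbation_rate >= 0, word_perturbation_rate <= 1,
            is.numeric(seed))
  structure(list(n_stories = as.integer(n_stories),
                 entities_per_story = as.integer(entities_per_story),
                 junk_sentence_rate = junk_sentence_rate,
                 word_perturbation_rate = word_perturbation_rate,
                 html_fluff = isTRUE(html_fluff), seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic story file with a ground-truth manifest
#'
#' Emulates the statistical shape of scraped story files: each story has a
#' short masthead line, optional HTML fluff, boilerplate junk sentences
#' drawn from the irrelevant-word vocabulary, and `entities_per_story`
#' planted sentences built from the taxonomy's own equivalence-set members
#' (see [plant_sentence()]). The manifest records every planted entity, so
#' extraction results can be scored exactly against ground truth.
#'
#' Fully deterministic in `spec$seed`. Perturbation draws one uniform per
#' word regardless of rate, so fixtures generated at different
#' `word_perturbation_rate` but the same seed perturb nested word sets —
#' which is what makes "recovery never increases with the perturbation
#' rate" a meaningful property. Region names carry a suffix that keeps them
#' outside the taxonomy's pseudo-word lengths, so location words can never
#' collide with equivalence-set members.
#'
#' @param spec A [fixture_spec()].
#' @param taxonomy An `emat_taxonomy` (non-empty).
#' @param stories_path,manifest_path Optional output paths (delimited story
#'   file; tab-separated manifest).
#' @return List: `stories` (`emat_story_file` tibble), `manifest` (tibble,
#'   one row per planted entity, `n_stories * entities_per_story` rows),
#'   `groups`, `regions` (character lexicons covering every planted
#'   actor/region).
#' @export
generate_story_file <- function(spec, taxonomy, stories_path = NULL,
                                manifest_path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"), nrow(taxonomy) >= 1L)
  actors <- unique(unlist(lapply(taxonomy$actors, function(a)
    if (length(a)) a[1] else character())))
  if (!length(actors)) actors <- "Field Authority"
  region_vocab <- make_vocab(8L, spec$seed + 7L)
  regions <- paste0(tools::toTitleCase(region_vocab), "land Plains")

  with_seed(spec$seed, {
    texts <- character(spec$n_stories)
    manifest <- list()
    for (s in seq_len(spec$n_stories)) {
      k <- min(spec$entities_per_story, nrow(taxonomy))
      acts <- if (k) sample(nrow(taxonomy), k) else integer()
      sents <- character()
      emit_junk <- function(sents) {
        run <- 0L  # at most 5 consecutive junk sentences per slot
        while (run < 5L && stats::runif(1) < spec$junk_sentence_rate) {
          sents <- c(sents, junk_sentence())
          run <- run + 1L
        }
        sents
      }
      for (a in acts) {
        sents <- emit_junk(sents)
        planted <- plant_sentence(
          taxonomy[a, ],
          actor = sample(actors, 1L),
          region = sample(regions, 1L),
          date = as.Date("2015-01-01") + sample.int(3000L, 1L),
          perturbation = spec$word_perturbation_rate)
        sents <- c(sents, planted$sentence)
        manifest[[length(manifest) + 1L]] <-
          dplyr::mutate(planted$truth, story_id = s, .before = 1L)
      }
      sents <- emit_junk(sents)
      masthead <- sprintf("The %s Daily", sample(regions, 1L))
      if (spec$html_fluff) {
        texts[s] <- paste0(
          "<html><head><title>", masthead, "</title>",
          "<script>var tracker = 1;</script>",
          "<style>.wrapper { color: red }</style></head><body>\n",
          "<div class=\"header\">", masthead, "</div>\n",
          paste0("<p>", sents, "</p>", collapse = "\n"),
          "\n<div class=\"footer\">", junk_sentence(), "</div>",
          "</body></html>")
      } else {
        texts[s] <- paste(c(masthead, sents), collapse = "\n")
      }
    }
    stories <- new_story_file(tibble::tibble(
      story_id = seq_len(spec$n_stories), text = texts))
    manifest <- if (length(manifest)) dplyr::bind_rows(manifest) else
      tibble::tibble(story_id = integer(), action_id = integer())
    if (!is.null(stories_path)) write_story_file(stories, stories_path)
    if (!is.null(manifest_path)) {
      utils::write.table(manifest, manifest_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(stories = stories, manifest = manifest, groups = actors,
         regions = regions)
  })
}
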
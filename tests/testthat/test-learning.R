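make_learning_stories <- function() {
  tibble::tibble(story_id = 1:2, text = c(
    paste("Farmers reported that elephants destroyed fields near the river.",
          "The fence by the gate was smashed by elephants overnight.",
          "Rangers said the herd moved on by the morning."),
    paste("Another plot of maize was smashed by elephants in the valley.",
          "A third field was smashed by elephants at the far boundary.")))
}

test_that("phrase search returns every case-insensitive usage with context", {
  stories <- make_learning_stories()
  hits <- find_phrase_contexts("elephants destroyed fields", stories)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$story_id, 1L)
  hits3 <- find_phrase_contexts("smashed by elephants", stories)
  expect_equal(nrow(hits3), 3L)
  expect_true(all(grepl("smashed by elephants", tolower(hits3$sentence),
                        fixed = TRUE)))
  # context window spans neighbouring sentences
  expect_match(hits3$context[1], "Rangers said")
  expect_equal(nrow(find_phrase_contexts("absent phrase", stories)), 0L)
  expect_error(find_phrase_contexts("one two three four five", stories),
               "one to four")
})

test_that("learning candidates fire on the SIMP band and on SIMD dominance", {
  cfg <- extraction_config()
  base <- tibble::tibble(
    sentence = c("band", "dominance", "neither", "band"),
    cluster = list(1L, 1L, 1L, 1L),
    verb = "arrested", object = NA_character_, prep = NA_character_,
    object_raw = c(NA, "five poachers", NA, NA),
    prep_raw = c("in the national park", NA, "to town", "in the national park"),
    actionD_raw = c(NA, 1L, NA, NA), simd_raw = c(0, 0.97, 0.2, 0),
    actionP_raw = c(2L, NA, 2L, 2L), simp_raw = c(0.75, 0.3, 0.85, 0.75),
    simd = 0, simp = 0)
  cand <- detect_candidates(base, cfg)
  expect_setequal(cand$trigger, c("simp_band", "simd_gt_simp"))
  band <- cand[cand$trigger == "simp_band", ]
  expect_true(all(band$simp >= cfg$learn_low & band$simp < cfg$prep_accept))
  expect_equal(band$action_id, 2L)          # duplicates collapsed: one row
  expect_equal(nrow(band), 1L)
  dom <- cand[cand$trigger == "simd_gt_simp", ]
  expect_equal(dom$sentence, "dominance")
  expect_equal(dom$action_id, 1L)
  expect_false("neither" %in% cand$sentence) # 0.85 is above the band
})

test_that("a banded near-miss becomes extractable after applying its suggestion", {
  tax <- emat_taxonomy(1L, "militaristic", "arrest poachers",
                       verbs = list("arrested"),
                       objects = list(character()),
                       preps = list("in the national park area"))
  sent <- "Two of the poachers were arrested in the national park."
  p <- parse_sentence(sent, verb_lexicon(tax))
  tr <- extract_entity_from_sentence(p, tax)
  expect_false(tr$accepted)
  # best prep similarity sits in the learning band: 0.8 * tanh(5)
  expect_equal(tr$simp_raw, 0.8 * tanh(5), tolerance = 1e-10)
  tr$story_id <- 1L; tr$sentence_index <- 1L
  cand <- detect_candidates(tr)
  expect_equal(cand$trigger, "simp_band")
  expect_equal(cand$action_id, 1L)
  report <- render_candidate_report(cand, tax)
  expect_match(report, "add_equivalence_member", fixed = TRUE)
  expect_match(report, cand$prep, fixed = TRUE)
  # apply the suggestion; the same sentence now extracts
  tax2 <- add_equivalence_member(tax, 1L, "prep", cand$prep)
  tr2 <- extract_entity_from_sentence(p, tax2)
  expect_true(tr2$accepted)
  expect_equal(tr2$action_id, 1L)
  expect_equal(render_candidate_report(cand[0, ], tax), "")
})

test_that("candidate detection is a deterministic function of the traces", {
  tax <- generate_toy_taxonomy(2, vocab_seed = 8)
  fx <- generate_story_file(fixture_spec(6, 2, 0.3, 0.15, TRUE, seed = 13),
                            tax)
  db <- parse_stories(fx$stories, tax, fx$groups, fx$regions)
  c1 <- detect_candidates(db$traces)
  c2 <- detect_candidates(db$traces)
  expect_identical(c1, c2)
  if (nrow(c1)) {
    expect_false(any(duplicated(paste(c1$sentence, c1$action_id,
                                      c1$trigger))))
  }
})
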
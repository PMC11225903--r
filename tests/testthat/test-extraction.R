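test_that("action clusters collect every gated action, best member first", {
  tax <- arrest_taxonomy()
  tax2 <- add_action(tax, "detain suspects", "militaristic", verb = "arrested")
  cl <- build_action_cluster("arrested", tax2)
  expect_setequal(cl$cluster, c(1L, 3L))
  expect_equal(cl$best_score, 1.0)
  expect_equal(cl$best_action, 1L)  # tie on 1.0 -> lowest action_id
  none <- build_action_cluster("bloomed", tax2)
  expect_true(is.na(none$best_action))
  expect_length(none$cluster, 0L)
})

test_that("the cascade accepts via object dominance on the example sentence", {
  tax <- arrest_taxonomy()[1, ]
  p <- parse_sentence(POACHER_SENTENCE, verb_lexicon(tax))
  tr <- extract_entity_from_sentence(p, tax)
  expect_true(tr$accepted)
  expect_equal(tr$action_id, 1L)
  expect_equal(tr$rule, "object_over_prep")
  expect_equal(tr$simd, tanh(2))        # "five poachers" identity
  expect_lt(tr$simp, 0.8)               # no prep member close enough
})

test_that("the cascade rejects when neither object nor prep matches", {
  tax <- emat_taxonomy(1L, "militaristic", "arrest poachers",
                       verbs = list("arrested"),
                       objects = list("contraband ivory"),
                       preps = list("across the border"))
  p <- parse_sentence(POACHER_SENTENCE, verb_lexicon(tax))
  tr <- extract_entity_from_sentence(p, tax)
  expect_false(tr$accepted)
  expect_equal(tr$rule, "no_dp")
})

test_that("an identical prep member accepts through the SIMP rule", {
  tax <- emat_taxonomy(1L, "militaristic", "sentence offenders",
                       verbs = list("sentenced"),
                       objects = list(character()),
                       preps = list("to prison"))
  p <- parse_sentence(POACHER_SENTENCE, verb_lexicon(tax))
  tr <- extract_entity_from_sentence(p, tax)
  expect_true(tr$accepted)
  expect_equal(tr$rule, "prep_accept")
  expect_gt(tr$simp, 0.8)
})

test_that("story tagging finds dates, groups and regions independently", {
  txt <- paste("Kenya Wildlife Services confirmed the arrests on June 10,",
               "2019 near Tsavo West.")
  tg <- tag_story(txt, groups = "Kenya Wildlife Services",
                  regions = c("Tsavo", "Tsavo West"))
  expect_equal(tg$date, as.Date("2019-06-10"))
  expect_equal(tg$group_hits$name, "Kenya Wildlife Services")
  expect_equal(tg$region_hits$name, "Tsavo West")  # longest match wins
  expect_equal(tag_story("report of 10 June 2019 patrol")$date,
               as.Date("2019-06-10"))
  expect_equal(tag_story("posted 2019-06-10 by admin")$date,
               as.Date("2019-06-10"))
  expect_equal(tag_story('<meta content="2020-02-01"> June 10, 2019')$date,
               as.Date("2020-02-01"))  # meta tag checked first
  tg0 <- tag_story("no date here at all")
  expect_true(is.na(tg0$date))
  expect_equal(nrow(tg0$group_hits), 0L)
})

test_that("actor and target attribution follows the nearest-hit rules", {
  tax <- arrest_taxonomy()
  toks <- tokenize("Kenya Wildlife Services arrested five poachers in Tsavo")
  tags <- tag_story("irrelevant", groups = "Kenya Wildlife Services",
                    regions = "Tsavo")
  at <- assign_actor_target(toks, verb_start = 4L,
                            groups = "Kenya Wildlife Services",
                            regions = "Tsavo", story_tags = tags,
                            action = tax[1, ])
  expect_equal(at$actor, "Kenya Wildlife Services")
  expect_equal(at$target, "Tsavo")
  expect_equal(at$actor_rule, "sentence")
  # archetype fallback
  empty_tags <- tag_story("nothing", character(), character())
  at2 <- assign_actor_target(tokenize("poachers were arrested quickly"), 3L,
                             character(), character(), empty_tags, tax[1, ])
  expect_equal(at2$actor, "rangers")
  expect_equal(at2$actor_rule, "archetype")
  expect_true(is.na(at2$target))
  # no archetypes either
  no_act <- emat_taxonomy(9L, "ecological", "bloom", verbs = list("bloomed"))
  at3 <- assign_actor_target(tokenize("algae bloomed overnight"), 2L,
                             character(), character(), empty_tags,
                             no_act[1, ])
  expect_true(is.na(at3$actor))
})

test_that("duplicate removal keeps first occurrences and is idempotent", {
  e <- tibble::tibble(
    action_id = c(1L, 1L, 2L, 1L, 1L), story_id = 1L,
    date = as.Date("2019-06-10"), actor = "kws", target = "tsavo")
  d <- deduplicate(e)
  expect_equal(d$action_id, c(1L, 2L))
  expect_identical(deduplicate(d), d)
  uniq <- tibble::tibble(action_id = 1:3, story_id = 1L,
                         date = as.Date("2019-06-10"), actor = "a",
                         target = "b")
  expect_identical(deduplicate(uniq), uniq)
})

test_that("boilerplate-only stories fail parsing without aborting the run", {
  tax <- generate_toy_taxonomy(1, vocab_seed = 3)
  junk <- tibble::tibble(
    story_id = 1:2,
    text = c("div class wrapper sidebar\nlogin header navigation",
             "copyright republish subscription\nstylesheet content column"))
  db <- parse_stories(junk, tax)
  expect_equal(nrow(db$entities), 0L)
  expect_equal(sort(db$parsefailed$story_id), 1:2)
  expect_match(db$parsefailed$reason, "no content sentences", all = TRUE)
})

test_that("identical inputs yield byte-identical output files", {
  tax <- generate_toy_taxonomy(2, vocab_seed = 2)
  fx <- generate_story_file(fixture_spec(6, 2, 0.3, 0.05, TRUE, seed = 11),
                            tax)
  outs <- list(withr::local_tempdir(), withr::local_tempdir())
  for (d in outs) {
    parse_stories(fx$stories, tax, fx$groups, fx$regions,
                  out_entities = file.path(d, "ents.dat"),
                  out_sdb = file.path(d, "sdb.dat"),
                  out_parsefailed = file.path(d, "parsefailed.dat"),
                  out_sample = file.path(d, "check.dat"))
  }
  for (f in c("ents.dat", "sdb.dat", "parsefailed.dat", "check.dat")) {
    a <- file.path(outs[[1]], f); b <- file.path(outs[[2]], f)
    expect_identical(readBin(a, "raw", file.size(a)),
                     readBin(b, "raw", file.size(b)))
  }
})

test_that("extraction distributes over story-file concatenation", {
  tax <- generate_toy_taxonomy(2, vocab_seed = 2)
  fa <- generate_story_file(fixture_spec(4, 1, 0.2, 0, TRUE, seed = 5), tax)
  fb <- generate_story_file(fixture_spec(3, 1, 0.2, 0, TRUE, seed = 6), tax)
  groups <- union(fa$groups, fb$groups)
  regions <- union(fa$regions, fb$regions)
  pa <- withr::local_tempfile(); pb <- withr::local_tempfile()
  write_story_file(fa$stories, pa); write_story_file(fb$stories, pb)
  pc <- withr::local_tempfile()
  concatenate_story_files(c(pa, pb), pc)

  db_a <- parse_stories(pa, tax, groups, regions)
  db_b <- parse_stories(pb, tax, groups, regions)
  db_c <- parse_stories(pc, tax, groups, regions)
  pre_dedup <- function(db) dplyr::bind_rows(db$per_story)
  sep <- dplyr::bind_rows(pre_dedup(db_a),
                          dplyr::mutate(pre_dedup(db_b),
                                        story_id = story_id + 4L))
  expect_equal(as.data.frame(pre_dedup(db_c)), as.data.frame(sep))
})

test_that("accepted traces always satisfy the cascade's acceptance condition", {
  tax <- generate_toy_taxonomy(2, vocab_seed = 4)
  fx <- generate_story_file(fixture_spec(8, 2, 0.3, 0.1, TRUE, seed = 9), tax)
  db <- parse_stories(fx$stories, tax, fx$groups, fx$regions)
  cfg <- extraction_config()
  tr <- db$traces[db$traces$accepted, ]
  expect_gt(nrow(tr), 0L)
  expect_true(all(tr$verb_score > cfg$verb_gate))
  expect_true(all(tr$simp > cfg$prep_accept | tr$simd > tr$simp))
})
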
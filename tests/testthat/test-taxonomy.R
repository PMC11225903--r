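test_that("taxonomy round-trips through the plain-text dialect byte-identically", {
  tax <- arrest_taxonomy()
  d1 <- withr::local_tempfile(); e1 <- withr::local_tempfile()
  d2 <- withr::local_tempfile(); e2 <- withr::local_tempfile()
  write_taxonomy(tax, d1, e1)
  back <- read_taxonomy(d1, e1)
  expect_equal(nrow(back), 2L)
  expect_identical(back$verbs, tax$verbs)
  expect_identical(back$objects, tax$objects)
  expect_identical(back$label, tax$label)
  write_taxonomy(back, d2, e2)
  expect_identical(readBin(d1, "raw", file.size(d1)),
                   readBin(d2, "raw", file.size(d2)))
  expect_identical(readBin(e1, "raw", file.size(e1)),
                   readBin(e2, "raw", file.size(e2)))
})

test_that("reader warns on one-sided records and errors on malformed lines", {
  def <- write_tmp_lines(c("# comment", "1\tmilitaristic\tarrest poachers\trangers"))
  eq_unknown <- write_tmp_lines(c("9\tverb\tarrest"))
  expect_warning(
    expect_warning(tax <- read_taxonomy(def, eq_unknown),
                   "unknown action id 9"),
    "without equivalence sets")
  expect_equal(nrow(tax), 1L)
  expect_length(tax$verbs[[1]], 0L)

  eq_ok <- write_tmp_lines("1\tverb\tarrest|arrested")
  expect_silent(tax2 <- read_taxonomy(def, eq_ok))
  expect_identical(tax2$verbs[[1]], c("arrest", "arrested"))

  bad <- write_tmp_lines("1 militaristic no tabs here")
  err <- tryCatch(read_taxonomy(bad, eq_ok), error = identity)
  expect_match(conditionMessage(err), ":1: expected 3 tab-separated fields")
  expect_match(conditionMessage(err), basename(bad), fixed = TRUE)

  bad_cat <- write_tmp_lines("1\tnaval\tblockade")
  expect_error(read_taxonomy(bad_cat, eq_ok), "unknown category 'naval'")
})

test_that("category counts cover all five categories and sum to the total", {
  tax <- arrest_taxonomy()
  cc <- category_counts(tax)
  expect_setequal(cc$category, emat_categories)
  expect_equal(sum(cc$n), nrow(tax))
  expect_equal(cc$n[cc$category == "militaristic"], 2L)

  empty <- emat_taxonomy()
  expect_true(all(category_counts(empty)$n == 0L))

  # property: totals equal row count for generated taxonomies
  for (seed in 1:4) {
    t <- generate_toy_taxonomy(sample(1:4, 1), vocab_seed = seed)
    expect_equal(sum(category_counts(t)$n), nrow(t))
    expect_true(all(category_counts(t)$n == nrow(t) / 5L))
  }
})

test_that("equivalence-set membership grows idempotently and locally", {
  tax <- arrest_taxonomy()
  # the learning example: a new verb and a long object phrase for an
  # existing "tighten laws"-style action
  tax <- add_action(tax, "tighten wildlife agreement or laws", "diplomatic",
                    verb = "tightened")
  id <- tax$action_id[tax$label == "tighten wildlife agreement or laws"]
  before <- tax
  tax <- add_equivalence_member(tax, id, "verb", "enacted")
  expect_length(tax$verbs[[match(id, tax$action_id)]], 2L)
  tax <- add_equivalence_member(
    tax, id, "object",
    "tough new laws that make ivory poaching and trafficking punishable")
  expect_length(tax$objects[[match(id, tax$action_id)]], 1L)
  # idempotent
  again <- add_equivalence_member(tax, id, "verb", "enacted")
  expect_identical(again, tax)
  # only the addressed set changed
  i <- match(id, tax$action_id)
  expect_identical(tax$preps[[i]], before$preps[[i]])
  expect_identical(tax$verbs[-i], before$verbs[-i])
  expect_error(add_equivalence_member(tax, 999L, "verb", "x"),
               "unknown action_id")
})

test_that("new actions start from the sentence's own phrases", {
  tax <- arrest_taxonomy()
  n0 <- category_counts(tax)
  tax2 <- add_action(tax, "Develop new technology to combat wildlife trafficking",
                     "ecosystem_directed", verb = "uses",
                     object = "modern technology and sophisticated data analysis",
                     prep = "to predict poaching plots")
  new <- tax2[nrow(tax2), ]
  expect_identical(new$action_id, max(tax$action_id) + 1L)
  expect_identical(new$verbs[[1]], "uses")
  expect_identical(new$objects[[1]],
                   "modern technology and sophisticated data analysis")
  expect_identical(new$preps[[1]], "to predict poaching plots")
  n1 <- category_counts(tax2)
  expect_equal(n1$n[n1$category == "ecosystem_directed"],
               n0$n[n0$category == "ecosystem_directed"] + 1L)
  # no prep -> empty set; duplicate label -> error
  tax3 <- add_action(tax, "verb only action", "ecological", verb = "bloomed")
  expect_length(tax3$preps[[nrow(tax3)]], 0L)
  expect_error(add_action(tax2, "arrest poachers", "militaristic", "grab"),
               "already exists")
})

test_that("the lint rule flags short object/prep members", {
  tax <- arrest_taxonomy()
  tax <- add_action(tax, "predictive patrol", "ecosystem_directed",
                    verb = "uses",
                    object = "modern technology and sophisticated data analysis tools",
                    prep = "to predict poaching plots")
  warns <- lint_equivalence_sets(tax, min_words = 4L)
  # the 4-token prep is flagged, the 7-token object is not
  expect_true("to predict poaching plots" %in% warns$phrase)
  expect_false(any(warns$n_tokens > 4L))
  expect_false("modern technology and sophisticated data analysis tools" %in%
                 warns$phrase)
  expect_equal(nrow(lint_equivalence_sets(emat_taxonomy())), 0L)
})

test_that("lexicons drop comments and case-folded duplicates", {
  p <- write_tmp_lines(c("# groups", "Kenya Wildlife Services", "",
                         "kenya wildlife services", "SANParks"))
  lex <- read_lexicon(p)
  expect_identical(lex, c("Kenya Wildlife Services", "SANParks"))
})
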
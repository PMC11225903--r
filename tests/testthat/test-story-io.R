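test_that("story files concatenate with one delimiter per input", {
  s1 <- write_tmp_lines("Rangers on patrol found snares.")
  s2 <- write_tmp_lines(c("A court sentenced two men.", "They appealed."))
  out <- withr::local_tempfile()
  sf <- concatenate_story_files(c(s1, s2), out)
  expect_equal(nrow(sf), 2L)
  expect_equal(sum(readLines(out) == "beginarticle 0"), 2L)
  # already-delimited input is not double-delimited
  out2 <- withr::local_tempfile()
  sf2 <- concatenate_story_files(out, out2)
  expect_equal(sum(readLines(out2) == "beginarticle 0"), 2L)
  expect_equal(nrow(sf2), 2L)
  # empty input list -> empty file, zero stories
  out3 <- withr::local_tempfile()
  expect_equal(nrow(concatenate_story_files(character(), out3)), 0L)
  expect_error(concatenate_story_files("no/such/file.txt", out3),
               "no/such/file.txt")
})

test_that("reading splits on delimiter lines, keeping leading text", {
  p <- write_tmp_lines(c("beginarticle 0", "one", "beginarticle 0", "two",
                         "beginarticle 0", "three"))
  expect_equal(nrow(read_story_file(p)), 3L)
  p2 <- write_tmp_lines(c("stray header text", "beginarticle 0", "one"))
  sf <- read_story_file(p2)
  expect_equal(nrow(sf), 2L)
  expect_equal(sf$text[1], "stray header text")
  # round trip preserves count and raw text
  out <- withr::local_tempfile()
  write_story_file(sf, out)
  expect_identical(read_story_file(out)$text, sf$text)
})

test_that("HTML stripping keeps text, drops blocklisted elements wholesale", {
  expect_equal(strip_html("<p>Poachers <b>arrested</b>.</p>"),
               "Poachers arrested.")
  expect_equal(strip_html("<script>var x=1;</script>Text"), "Text")
  expect_equal(
    strip_html("<div><script>var x=1;</script>Keep <b>me</b></div>"),
    "Keep me")
  expect_match(strip_html("Fish &amp; chips"), "Fish & chips", fixed = TRUE)
  # malformed markup never raises
  expect_no_error(strip_html("<div <p Unclosed <b>bold"))
  expect_equal(strip_html(""), "")
})

test_that("source detection prefers URL domain, then short masthead", {
  expect_equal(detect_source("read https://www.example-news.co.ke/article now"),
               "example-news.co.ke")
  expect_equal(detect_source("Daily Nation\nLong body text follows here."),
               "Daily Nation")
  long_line <- paste(rep("word", 12), collapse = " ")
  expect_equal(detect_source(long_line), "unknown")
})

test_that("sentence segmentation respects abbreviations, dates and decimals", {
  expect_length(segment_sentences(POACHER_SENTENCE), 1L)
  expect_length(segment_sentences("It rained. Poachers fled."), 2L)
  expect_length(segment_sentences("Dr. Okoye spoke. Mr. Njoro listened."), 2L)
  expect_length(segment_sentences("A. B. saw it happen"), 1L)
  expect_length(segment_sentences("Fines rose 3.5 percent in 2019."), 1L)
  expect_length(segment_sentences(""), 0L)
})

test_that("the content filter counts common-word occurrences and boilerplate fraction", {
  expect_true(is_content_sentence(
    "the poachers were arrested at the park with rifles"))
  expect_false(is_content_sentence(
    "div class wrapper sidebar navigation header"))
  expect_false(is_content_sentence("copyright"))
  # the http: entry matches any http-prefixed token
  expect_false(is_content_sentence(
    "subscribe login http://x.com/a https://y.org wrapper"))
  # order-invariance: filter depends only on the token multiset
  set.seed(5)
  toks <- tokenize("the rangers found a snare near the gate on patrol")
  for (i in 1:10) {
    expect_identical(is_content_sentence(sample(toks)),
                     is_content_sentence(toks))
  }
})

test_that("content fragments are order-preserving and idempotent", {
  story <- paste("The rangers were out on the a patrol.",
                 "div class wrapper header sidebar login.",
                 "They found a snare by the gate of the park.",
                 "copyright republish subscription stylesheet content.",
                 "Both of the men were arrested at the scene.")
  frag <- content_fragment(story)
  expect_length(frag, 3L)
  refrag <- frag[vapply(frag, is_content_sentence, logical(1))]
  expect_identical(refrag, frag)
  expect_length(content_fragment("div class wrapper. login header sidebar."),
                0L)
})

test_that("ecological data sets format as the fixed template sentence", {
  expect_identical(
    format_eco_story("Kenya Wildlife Services", "abundance", "cheetah",
                     "Laikipia", "Kenya", as.Date("2009-01-01"),
                     as.Date("2013-12-31")),
    paste("Kenya Wildlife Services collected abundance data on cheetah in",
          "Laikipia, Kenya during the period 2009-01-01 to 2013-12-31."))
  expect_match(format_eco_story("TerraServer", "NDVI", "N/A", "Tsavo",
                                "Kenya", "2019-01-01", "2019-12-31"),
               "NDVI data on N/A in Tsavo", fixed = TRUE)
  expect_error(format_eco_story("KWS", "biomass", "cheetah", "Tsavo",
                                "Kenya", "2019-01-01", "2019-12-31"),
               "data_type")
})
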
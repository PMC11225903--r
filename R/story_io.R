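STORY_DELIM <- "beginarticle 0"

#' Textual-content filter configuration
#'
#' A sentence counts as textual content when it contains at least
#' `min_common` occurrences of a short list of common English function words
#' and when fewer than `max_irrelevant_frac` of its tokens come from a list
#' of web-boilerplate words. The two default word lists target the HTML/CSS
#' debris that survives tag stripping in scraped news pages.
#'
#' @param common_words Common-word list (17 function words by default).
#' @param irrelevant_words Boilerplate list; the entry `"http:"` matches any
#'   token starting with `"http"`.
#' @param min_common Minimum count of common-word occurrences (default 3).
#' @param max_irrelevant_frac Sentences with at least this fraction of
#'   boilerplate tokens are dropped (default 0.80).
#' @return A list of class `content_filter_config`.
#' @export
content_filter_config <- function(
    common_words = c("the", "a", "of", "is", "by", "to", "be", "from", "and",
                     "have", "in", "that", "on", "with", "as", "at", "inside"),
    irrelevant_words = c("content", "copyright", "stylesheet", "subscribe",
                         "subscription", "login", "header", "sidebar",
                         "wrapper", "label", "navigation", "class", "column",
                         "http:", "republish", "div"),
    min_common = 3L, max_irrelevant_frac = 0.80) {
  stopifnot(min_common >= 1L, max_irrelevant_frac > 0,
            max_irrelevant_frac <= 1)
  structure(list(common_words = common_words,
                 irrelevant_words = irrelevant_words,
                 min_common = as.integer(min_common),
                 max_irrelevant_frac = max_irrelevant_frac),
            class = "content_filter_config")
}

new_story_file <- function(df, origin_path = NA_character_) {
  df <- tibble::as_tibble(df)
  attr(df, "origin_path") <- origin_path
  class(df) <- c("emat_story_file", class(df))
  df
}

#' Read a delimited story file
#'
#' Story files hold one or more scraped stories separated by lines exactly
#' equal to `beginarticle 0`. Text before the first delimiter, if any, is
#' returned as an extra leading story. An empty file yields zero stories.
#'
#' @param path Story-file path.
#' @return An `emat_story_file` tibble with columns `story_id` (ordinal from
#'   1) and `text` (raw story text, newlines preserved).
#' @export
read_story_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  story_file_from_lines(lines, origin_path = path)
}

story_file_from_lines <- function(lines, origin_path = NA_character_) {
  delims <- which(lines == STORY_DELIM)
  starts <- c(if (length(delims) == 0L || delims[1] > 1L) 0L, delims)
  texts <- character()
  for (k in seq_along(starts)) {
    from <- starts[k] + 1L
    to <- if (k < length(starts)) starts[k + 1L] - 1L else length(lines)
    chunk <- if (from > to) "" else paste(lines[from:to], collapse = "\n")
    texts <- c(texts, chunk)
  }
  # a leading chunk that is empty (file starts with the delimiter) is not a story
  if (length(starts) && starts[1] == 0L && !nzchar(trimws(texts[1]))) {
    texts <- texts[-1]
  }
  new_story_file(tibble::tibble(story_id = seq_along(texts), text = texts),
                 origin_path)
}

#' Write a story file
#'
#' Each story is preceded by a `beginarticle 0` delimiter line;
#' [read_story_file()] on the result recovers story count and text exactly.
#'
#' @param stories An `emat_story_file` tibble (or any tibble with a `text`
#'   column).
#' @param path Output path.
#' @return `stories`, invisibly.
#' @export
write_story_file <- function(stories, path) {
  lines <- unlist(lapply(stories$text, function(t) {
    c(STORY_DELIM, strsplit(t, "\n", fixed = TRUE)[[1]])
  }))
  if (is.null(lines)) lines <- character()
  writeLines(lines, path)
  invisible(stories)
}

#' Concatenate individual story files into one delimited story file
#'
#' Each input file becomes one story, prefixed by the `beginarticle 0`
#' delimiter; inputs that already start with the delimiter are not
#' double-delimited. Re-reading the output yields one story per input file.
#'
#' @param paths Ordered character vector of input files.
#' @param out_path Output story-file path.
#' @return The concatenated `emat_story_file`, invisibly.
#' @export
concatenate_story_files <- function(paths, out_path) {
  out <- character()
  for (p in paths) {
    if (!file.exists(p)) stop("cannot read story file: ", p, call. = FALSE)
    lines <- readLines(p, warn = FALSE)
    if (!length(lines) || lines[1] != STORY_DELIM) {
      lines <- c(STORY_DELIM, lines)
    }
    out <- c(out, lines)
  }
  writeLines(out, out_path)
  invisible(read_story_file(out_path))
}

#' Strip HTML markup from story text
#'
#' Elements whose tag is on the blocklist are removed wholesale (their text
#' disappears); every other tag is deleted but its text kept; character
#' entities are decoded. Parsing is best-effort via libxml2's HTML parser, so
#' malformed markup never raises; input without any markup passes through
#' with whitespace normalized per line.
#'
#' @param raw Raw story text (single string).
#' @param tag_blocklist Tags whose content is dropped entirely.
#' @return Plain text.
#' @export
strip_html <- function(raw, tag_blocklist = c("script", "style", "head",
                                              "nav", "footer", "form",
                                              "iframe")) {
  if (!nzchar(raw)) return("")
  if (!grepl("<[a-zA-Z!/]", raw)) {
    if (!grepl("&[a-zA-Z#][a-zA-Z0-9]*;", raw)) return(squeeze_ws(raw))
    # no markup, but entities to decode: parse a wrapped copy
    doc <- tryCatch(xml2::read_html(paste0("<p>", raw, "</p>")),
                    error = function(e) NULL)
    if (is.null(doc)) return(squeeze_ws(raw))
    return(squeeze_ws(xml2::xml_text(doc)))
  }
  doc <- tryCatch(xml2::read_html(raw), error = function(e) NULL)
  if (is.null(doc)) return(squeeze_ws(gsub("<[^>]*>", " ", raw)))
  if (length(tag_blocklist)) {
    xpath <- paste0("//", tag_blocklist, collapse = " | ")
    xml2::xml_remove(xml2::xml_find_all(doc, xpath))
  }
  # block-level elements become line breaks so sentences do not fuse
  blocks <- xml2::xml_find_all(
    doc, "//p | //br | //li | //h1 | //h2 | //h3 | //h4 | //tr | //div")
  for (b in blocks) {
    tryCatch(xml2::xml_add_sibling(b, xml2::read_xml("<x>\n</x>"),
                                   .where = "before"),
             error = function(e) NULL)
  }
  squeeze_ws(xml2::xml_text(doc))
}

squeeze_ws <- function(x) {
  lines <- strsplit(x, "\n", fixed = TRUE)[[1]]
  lines <- trimws(gsub("[ \t\r]+", " ", lines))
  paste(lines[nzchar(lines)], collapse = "\n")
}

#' Detect a story's reporting source
#'
#' The registrable domain of the first URL in the story if one is present;
#' otherwise the first non-empty line when it is short enough (at most 8
#' tokens) to be a masthead; otherwise `"unknown"`.
#'
#' @param story One story's text (single string), or a one-row story tibble.
#' @return A single string.
#' @export
detect_source <- function(story) {
  text <- if (is.data.frame(story)) story$text[[1]] else story
  m <- regmatches(text, regexpr("https?://[^[:space:]\"'<>]+", text))
  if (length(m) && nzchar(m)) {
    host <- sub("^https?://", "", m)
    host <- sub("[/?#].*$", "", host)
    host <- sub("^www\\.", "", host)
    if (nzchar(host)) return(host)
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  first <- lines[nzchar(lines)][1]
  if (!is.na(first) && length(tokenize(first)) <= 8L &&
      length(tokenize(first)) >= 1L) {
    return(first)
  }
  "unknown"
}

SENT_ABBREV <- c("mr", "mrs", "ms", "dr", "prof", "sr", "jr", "st", "no",
                 "vs", "etc", "e.g", "i.e", "u.s", "u.k", "u.n", "a.m", "p.m")

#' Split text into sentences
#'
#' Deterministic rule-based segmentation: a sentence ends at `.`, `?` or `!`
#' followed by whitespace and an uppercase letter or digit. A fixed
#' abbreviation list (Mr., Dr., U.S., e.g., ...) and decimal numbers never
#' end a sentence. Newlines without terminal punctuation also separate
#' sentences (scraped stories break at block boundaries).
#'
#' @param text A single string.
#' @return Character vector of sentences (trimmed, possibly empty vector).
#' @export
segment_sentences <- function(text) {
  if (!nzchar(trimws(text))) return(character())
  chunks <- strsplit(text, "\n+")[[1]]
  chunks <- trimws(chunks)
  chunks <- chunks[nzchar(chunks)]
  out <- character()
  for (chunk in chunks) {
    pos <- gregexpr("[.?!]+(?=\\s+[A-Z0-9])", chunk, perl = TRUE)[[1]]
    if (pos[1] == -1L) { out <- c(out, chunk); next }
    lens <- attr(pos, "match.length")
    cuts <- integer()
    for (k in seq_along(pos)) {
      end <- pos[k] + lens[k] - 1L
      before <- substr(chunk, 1, pos[k] - 1L)
      last_word <- tolower(sub("^.*?([[:alnum:].]+)$", "\\1", before))
      if (last_word %in% SENT_ABBREV) next          # abbreviation
      if (grepl("^[a-z]$", last_word)) next         # single initial "A."
      cuts <- c(cuts, end)
    }
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, nchar(chunk))
    pieces <- trimws(substring(chunk, starts, ends))
    out <- c(out, pieces[nzchar(pieces)])
  }
  out
}

#' Is a sentence textual content?
#'
#' @param sentence A sentence as a string or token vector.
#' @param cfg A [content_filter_config()].
#' @return `TRUE` when the sentence has at least `min_common` common-word
#'   occurrences and fewer than `max_irrelevant_frac` of its tokens are
#'   boilerplate. Order-invariant: depends only on the token multiset.
#' @export
is_content_sentence <- function(sentence, cfg = content_filter_config()) {
  toks <- if (length(sentence) > 1L) sentence else tokenize(sentence)
  if (!length(toks)) return(FALSE)
  n_common <- sum(toks %in% cfg$common_words)
  plain_irr <- setdiff(cfg$irrelevant_words, "http:")
  is_irr <- toks %in% plain_irr
  if ("http:" %in% cfg$irrelevant_words) {
    is_irr <- is_irr | startsWith(toks, "http")
  }
  n_common >= cfg$min_common &&
    (sum(is_irr) / length(toks)) < cfg$max_irrelevant_frac
}

#' Reduce a story to its textual-content sentences
#'
#' Tag-filters nothing itself; call [strip_html()] first for raw scrapes.
#' Idempotent, order-preserving.
#'
#' @param text Story text (single string).
#' @param cfg A [content_filter_config()].
#' @return Character vector of content sentences (possibly empty).
#' @export
content_fragment <- function(text, cfg = content_filter_config()) {
  sents <- segment_sentences(text)
  sents[vapply(sents, is_content_sentence, logical(1), cfg = cfg)]
}

ECO_DATA_TYPES <- c("abundance", "presence/absence", "capture-recapture",
                    "rainfall", "NDVI", "landuse")

#' Format an ecological data set as a one-sentence story
#'
#' Ecological data-set references (abundance surveys, remote-sensing
#' products, ...) enter the extraction pipeline as one-sentence stories of a
#' fixed template: `"<group> collected <type> data on <species> in <region>,
#' <country> during the period <start> to <end>."` For rainfall, NDVI and
#' landuse data the species slot is `"N/A"`.
#'
#' @param group Data-collecting group name.
#' @param data_type One of `r paste(ECO_DATA_TYPES, collapse = ", ")`.
#' @param species Species name, or `"N/A"`.
#' @param region,country Location.
#' @param startdate,enddate Dates (anything `format()`-able, printed as-is).
#' @return The template sentence.
#' @export
format_eco_story <- function(group, data_type, species, region, country,
                             startdate, enddate) {
  if (!data_type %in% ECO_DATA_TYPES) {
    stop("data_type must be one of: ", paste(ECO_DATA_TYPES, collapse = ", "),
         call. = FALSE)
  }
  sprintf("%s collected %s data on %s in %s, %s during the period %s to %s.",
          group, data_type, species, region, country,
          format(startdate), format(enddate))
}
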
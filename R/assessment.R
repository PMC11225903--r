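#' Write the extraction-assessment sample file
#'
#' Samples `k` stories (default 10) at evenly spaced line offsets of the
#' on-disk story file — the story containing line `floor(i * m / k)` for
#' `i = 0..k-1`, where `m` is the file's total line count; when two offsets
#' land in the same story the sampler skips forward so the stories are
#' distinct. Files with fewer than `k` stories are sampled whole. Each
#' sampled story's text is written followed by its extracted entities, for
#' a human to read and score. Deterministic: a pure function of the file's
#' line layout and `k`.
#'
#' @param stories An `emat_story_file` tibble or story-file path.
#' @param db An `emat_story_db` from [parse_stories()] (or `NULL` to write
#'   the texts alone).
#' @param k Number of stories to sample (default 10).
#' @param out_path Optional output path; omit to just get the sample.
#' @return Tibble of the sampled stories (`story_id`, `text`), invisibly
#'   when writing.
#' @export
write_assessment_sample <- function(stories, db = NULL, k = 10L,
                                    out_path = NULL) {
  if (is.character(stories) && length(stories) == 1L) {
    stories <- read_story_file(stories)
  }
  n_lines_per <- 1L + vapply(strsplit(stories$text, "\n", fixed = TRUE),
                             length, integer(1))  # delimiter + text lines
  start_line <- cumsum(c(1L, utils::head(n_lines_per, -1L)))
  m <- sum(n_lines_per)
  n <- nrow(stories)

  if (n <= k) {
    picked <- seq_len(n)
  } else {
    picked <- integer()
    for (i in seq_len(k) - 1L) {
      line <- max(1L, floor(i * m / k))
      s <- findInterval(line, start_line)
      while (s %in% picked && s < n) s <- s + 1L  # skip duplicates forward
      if (!s %in% picked) picked <- c(picked, s)
    }
  }
  sampled <- stories[picked, c("story_id", "text")]

  if (!is.null(out_path)) {
    lines <- character()
    for (j in seq_len(nrow(sampled))) {
      sid <- sampled$story_id[j]
      lines <- c(lines, sprintf("==== story %d ====", sid),
                 strsplit(sampled$text[j], "\n", fixed = TRUE)[[1]],
                 "---- extracted entities ----")
      if (!is.null(db)) {
        e <- db$entities[db$entities$story_id == sid, ]
        lines <- c(lines,
                   if (nrow(e)) sprintf("%d\t%s\t%s", e$action_id, e$label,
                                        ifelse(is.na(e$date), "NA",
                                               as.character(e$date)))
                   else "(none)")
      }
      lines <- c(lines, "")
    }
    writeLines(lines, out_path)
    return(invisible(sampled))
  }
  sampled
}

#' Score machine extractions against a human benchmark
#'
#' Using the human-extracted actions as truth, the machine can err in two
#' ways: missing an action, and extracting a *spurious* action absent from
#' the story. With `n_true` human actions, `r_correct` is the fraction of
#' them the machine also extracted and `r_spurious` is the ratio of spurious
#' machine extractions to `n_true`. An `r_correct` below about 70% signals
#' the algorithm or the equivalence sets need work on missed actions; an
#' `r_spurious` above about 40% signals equivalence-set members that are too
#' short or too ambiguous.
#'
#' The match criterion is same `story_id` and same `action_id` (dates and
#' actors are not compared — human benchmarks rarely annotate them
#' consistently); pass more columns via `match_on` for stricter matching.
#'
#' @param machine Machine-extracted entities (tibble with at least the
#'   `match_on` columns), e.g. `parse_stories(...)$entities`.
#' @param human Human benchmark (tibble with the `match_on` columns; one
#'   row per human-extracted action).
#' @param match_on Key columns (default `c("story_id", "action_id")`).
#' @param low_recall,high_spurious Advisory thresholds (defaults 0.70 and
#'   0.40).
#' @return An `emat_assessment` list: `n_true`, `n_correct`, `n_spurious`,
#'   `r_correct`, `r_spurious`, `flags` (character vector, possibly empty).
#' @export
score_against_benchmark <- function(machine, human,
                                    match_on = c("story_id", "action_id"),
                                    low_recall = 0.70,
                                    high_spurious = 0.40) {
  n_true <- nrow(human)
  if (!n_true) {
    stop("benchmark is empty: r_correct and r_spurious are undefined",
         call. = FALSE)
  }
  key <- function(df) do.call(paste, c(df[match_on], sep = "\r"))
  hk <- key(human); mk <- key(machine)
  n_correct <- sum(hk %in% mk)
  n_spurious <- sum(!mk %in% hk)
  r_correct <- n_correct / n_true
  r_spurious <- n_spurious / n_true
  flags <- c(
    if (r_correct < low_recall)
      sprintf("r_correct %.2f < %.2f: algorithm and/or equivalence sets are missing actions",
              r_correct, low_recall),
    if (r_spurious > high_spurious)
      sprintf("r_spurious %.2f > %.2f: equivalence-set members too short or ambiguous",
              r_spurious, high_spurious))
  structure(list(n_true = n_true, n_correct = n_correct,
                 n_spurious = n_spurious, r_correct = r_correct,
                 r_spurious = r_spurious, flags = flags %||% character(),
                 low_recall = low_recall, high_spurious = high_spurious),
            class = "emat_assessment")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.emat_assessment <- function(x, ...) {
  cat(sprintf("n_true = %d, r_correct = %.2f, r_spurious = %.2f\n",
              x$n_true, x$r_correct, x$r_spurious))
  for (f in x$flags) cat("  !", f, "\n")
  invisible(x)
}

#' @method tidy emat_assessment
#' @export
tidy.emat_assessment <- function(x, ...) {
  tibble::tibble(metric = c("r_correct", "r_spurious"),
                 estimate = c(x$r_correct, x$r_spurious),
                 numerator = c(x$n_correct, x$n_spurious),
                 n_true = x$n_true,
                 threshold = c(x$low_recall, x$high_spurious),
                 flagged = c(x$r_correct < x$low_recall,
                             x$r_spurious > x$high_spurious))
}

#' @method glance emat_assessment
#' @export
glance.emat_assessment <- function(x, ...) {
  tibble::tibble(n_true = x$n_true, n_correct = x$n_correct,
                 n_spurious = x$n_spurious, r_correct = x$r_correct,
                 r_spurious = x$r_spurious, n_flags = length(x$flags))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot assessment metrics against their advisory thresholds
#'
#' @param object An `emat_assessment`.
#' @param ... Unused.
#' @return A ggplot: the two ratios as bars with dashed advisory-threshold
#'   lines.
#' @method autoplot emat_assessment
#' @export
autoplot.emat_assessment <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$estimate,
                                  fill = .data$flagged)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$threshold,
                                        ymax = .data$threshold),
                           linetype = "dashed", width = 0.8) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(y = "ratio (relative to n_true)", x = NULL,
                  title = sprintf("extraction accuracy (n_true = %d)",
                                  object$n_true),
                  caption = "dashed: advisory thresholds (0.70 recall, 0.40 spurious)") +
    ggplot2::theme_minimal()
}
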
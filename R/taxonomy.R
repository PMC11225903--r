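#' @importFrom rlang .data
NULL

#' The five EMAT action categories
#' @export
emat_categories <- c("militaristic", "diplomatic", "economic",
                     "ecosystem_directed", "ecological")

new_taxonomy <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("action_id", "category", "label",
                  "actors", "verbs", "objects", "preps") %in% names(df)))
  if (anyDuplicated(df$action_id)) {
    stop("duplicate action_id in taxonomy", call. = FALSE)
  }
  bad <- setdiff(unique(df$category), emat_categories)
  if (length(bad)) {
    stop("unknown categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("emat_taxonomy", class(df))
  df
}

#' Build a taxonomy tibble from per-action fields
#'
#' An EMAT taxonomy is a tibble with one row per action: integer `action_id`,
#' `category` (one of [emat_categories]), `label`, and list-columns `actors`,
#' `verbs`, `objects`, `preps` holding character vectors. The three phrase
#' columns are the action's equivalence sets (semantically interchangeable
#' m-word verbs, direct-object phrases, prepositional phrases); every action
#' has a non-empty verb set, while object/prep sets may be empty.
#'
#' @param action_id Integer ids (unique).
#' @param category Character, one of [emat_categories] per action.
#' @param label Human-readable action names.
#' @param actors,verbs,objects,preps Lists of character vectors (recycled if
#'   a single vector is given for one action).
#' @return An `emat_taxonomy` tibble.
#' @export
#' @examples
#' emat_taxonomy(1L, "militaristic", "arrest poachers",
#'               verbs = list(c("arrest", "arrested")),
#'               objects = list("poachers"))
emat_taxonomy <- function(action_id = integer(), category = character(),
                          label = character(), actors = list(),
                          verbs = list(), objects = list(), preps = list()) {
  n <- length(action_id)
  pad <- function(l) {
    if (!length(l)) return(rep(list(character()), n))
    if (is.character(l)) l <- list(l)
    rep_len(l, n)
  }
  norm_sets <- function(l) {
    lapply(pad(l), function(v) unique(normalize_phrase(v[nzchar(v)])))
  }
  df <- tibble::tibble(
    action_id = as.integer(action_id),
    category = as.character(category),
    label = as.character(label),
    actors = pad(actors),
    verbs = norm_sets(verbs),
    objects = norm_sets(objects),
    preps = norm_sets(preps)
  )
  # actions normally carry a non-empty verb set; one-sided records read from
  # mismatched files are kept (with their reader warning) but cannot match
  new_taxonomy(df)
}

#' Read a taxonomy from a definition file and an equivalence-set file
#'
#' The default `"tsv"` dialect is the package's documented plain-text layout
#' (see `vignette("emat-extraction")`): the definition file has one
#' tab-separated record per action, `id  category  label  actor1|actor2|...`;
#' the equivalence file has records `id  role  phrase1|phrase2|...` with role
#' one of `verb`, `object`, `prep`. `#`-prefixed lines and blank lines are
#' ignored in both. Supplementary files in another layout can be adapted by
#' passing a reader function as `dialect`.
#'
#' Actions present in only one of the two files are kept (with empty
#' equivalence sets) and a warning is emitted; equivalence records naming an
#' unknown action are dropped with a warning.
#'
#' @param definition_path Path to the action-definition file.
#' @param equivalence_path Path to the parsed-equivalence-sets file.
#' @param dialect `"tsv"`, or a function
#'   `function(definition_lines, equivalence_lines) -> emat_taxonomy` used as
#'   a dialect plug-in for externally supplied files.
#' @return An `emat_taxonomy` tibble.
#' @export
read_taxonomy <- function(definition_path, equivalence_path, dialect = "tsv") {
  for (p in c(definition_path, equivalence_path)) {
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  }
  def_lines <- readLines(definition_path, warn = FALSE)
  eq_lines <- readLines(equivalence_path, warn = FALSE)
  if (is.function(dialect)) return(dialect(def_lines, eq_lines))
  if (!identical(dialect, "tsv")) {
    stop("unknown dialect: ", dialect, call. = FALSE)
  }

  content <- function(lines) {
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    which(keep)
  }
  parse_fields <- function(line, n_expect, path, lineno) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < n_expect) {
      stop(sprintf("%s:%d: expected %d tab-separated fields, got %d (%s)",
                   path, lineno, n_expect, length(f), line), call. = FALSE)
    }
    f
  }
  split_bar <- function(x) {
    if (!nzchar(trimws(x))) return(character())
    trimws(strsplit(x, "|", fixed = TRUE)[[1]])
  }

  defs <- list()
  for (i in content(def_lines)) {
    f <- parse_fields(def_lines[i], 3L, definition_path, i)
    id <- suppressWarnings(as.integer(f[1]))
    if (is.na(id)) {
      stop(sprintf("%s:%d: action id must be an integer, got '%s'",
                   definition_path, i, f[1]), call. = FALSE)
    }
    if (!f[2] %in% emat_categories) {
      stop(sprintf("%s:%d: unknown category '%s'", definition_path, i, f[2]),
           call. = FALSE)
    }
    defs[[as.character(id)]] <- list(
      action_id = id, category = f[2], label = f[3],
      actors = if (length(f) >= 4L) split_bar(f[4]) else character())
  }

  sets <- list()
  roles <- c(verb = "verbs", object = "objects", prep = "preps")
  for (i in content(eq_lines)) {
    f <- parse_fields(eq_lines[i], 3L, equivalence_path, i)
    id <- f[1]
    if (!f[2] %in% names(roles)) {
      stop(sprintf("%s:%d: role must be verb/object/prep, got '%s'",
                   equivalence_path, i, f[2]), call. = FALSE)
    }
    if (is.null(defs[[id]])) {
      if (is.null(sets[[id]])) {
        warning("equivalence sets reference unknown action id ", id,
                "; entry ignored", call. = FALSE)
        sets[[id]] <- list()  # warn once per id
      }
      next
    }
    sets[[id]][[roles[[f[2]]]]] <- split_bar(f[3])
  }

  only_def <- setdiff(names(defs), names(sets)[lengths(sets) > 0])
  if (length(only_def)) {
    warning("actions without equivalence sets kept with empty sets: ",
            paste(only_def, collapse = ", "), call. = FALSE)
  }

  get_set <- function(id, role) {
    v <- sets[[id]][[role]]
    if (is.null(v)) character() else v
  }
  ids <- names(defs)
  emat_taxonomy(
    action_id = vapply(ids, function(i) defs[[i]]$action_id, integer(1)),
    category = vapply(ids, function(i) defs[[i]]$category, character(1)),
    label = vapply(ids, function(i) defs[[i]]$label, character(1)),
    actors = lapply(ids, function(i) defs[[i]]$actors),
    verbs = lapply(ids, function(i) get_set(i, "verbs")),
    objects = lapply(ids, function(i) get_set(i, "objects")),
    preps = lapply(ids, function(i) get_set(i, "preps"))
  )
}

#' Write a taxonomy in the package's plain-text dialect
#'
#' Inverse of [read_taxonomy()]'s `"tsv"` dialect; `read_taxonomy()` on the
#' written pair round-trips the taxonomy, and re-writing round-trips the
#' files byte-identically.
#'
#' @param taxonomy An `emat_taxonomy`.
#' @param definition_path,equivalence_path Output paths.
#' @return `taxonomy`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, definition_path, equivalence_path) {
  join <- function(v) paste(v, collapse = "|")
  def <- sprintf("%d\t%s\t%s\t%s", taxonomy$action_id, taxonomy$category,
                 taxonomy$label, vapply(taxonomy$actors, join, character(1)))
  eq <- character()
  role_map <- c(verb = "verbs", object = "objects", prep = "preps")
  for (i in seq_len(nrow(taxonomy))) {
    for (r in names(role_map)) {
      v <- taxonomy[[role_map[[r]]]][[i]]
      if (length(v)) {
        eq <- c(eq, sprintf("%d\t%s\t%s", taxonomy$action_id[i], r, join(v)))
      }
    }
  }
  writeLines(def, definition_path)
  writeLines(eq, equivalence_path)
  invisible(taxonomy)
}

#' Count actions per category
#'
#' @param taxonomy An `emat_taxonomy`.
#' @return A tibble with one row per category (all five categories always
#'   present) and columns `category`, `n`; `sum(n)` equals `nrow(taxonomy)`.
#' @export
category_counts <- function(taxonomy) {
  counts <- table(factor(taxonomy$category, levels = emat_categories))
  tibble::tibble(category = emat_categories, n = as.integer(counts))
}

#' Add a phrase to one of an action's equivalence sets
#'
#' Adding a phrase already present is a no-op; all other sets and actions are
#' untouched. This is the machine-applicable half of the human learning loop:
#' a reviewed learning candidate's verb/object/prep phrases are folded into
#' the existing action they describe.
#'
#' @param taxonomy An `emat_taxonomy`.
#' @param action_id Id of an existing action.
#' @param role `"verb"`, `"object"`, or `"prep"`.
#' @param phrase Phrase to add (normalized on entry).
#' @return The updated taxonomy.
#' @export
add_equivalence_member <- function(taxonomy, action_id, role, phrase) {
  role <- match.arg(role, c("verb", "object", "prep"))
  col <- c(verb = "verbs", object = "objects", prep = "preps")[[role]]
  i <- match(as.integer(action_id), taxonomy$action_id)
  if (is.na(i)) stop("unknown action_id: ", action_id, call. = FALSE)
  phrase <- normalize_phrase(phrase)
  if (!nzchar(phrase)) stop("phrase must be non-empty", call. = FALSE)
  if (!phrase %in% taxonomy[[col]][[i]]) {
    taxonomy[[col]][[i]] <- c(taxonomy[[col]][[i]], phrase)
  }
  taxonomy
}

#' Create a new action from a sentence's parsed components
#'
#' The new-action half of the learning loop: the sentence's m-word verb,
#' direct-object phrase and (if present) prepositional phrase become the
#' initial members of the new action's three equivalence sets. The new
#' `action_id` is one more than the current maximum.
#'
#' @param taxonomy An `emat_taxonomy`.
#' @param label New action label (must not already exist).
#' @param category One of [emat_categories].
#' @param verb Initial verb-set member (required).
#' @param object,prep Initial object/prep members; `NULL` or `""` leaves the
#'   set empty.
#' @param actors Archetypal actor names.
#' @return The taxonomy with one more row.
#' @export
add_action <- function(taxonomy, label, category, verb, object = NULL,
                       prep = NULL, actors = character()) {
  if (label %in% taxonomy$label) {
    stop("an action labelled '", label, "' already exists", call. = FALSE)
  }
  category <- match.arg(category, emat_categories)
  as_set <- function(p) {
    if (is.null(p) || !nzchar(p)) character() else normalize_phrase(p)
  }
  verb <- as_set(verb)
  if (!length(verb)) stop("`verb` must be non-empty", call. = FALSE)
  new_id <- if (nrow(taxonomy)) max(taxonomy$action_id) + 1L else 1L
  row <- emat_taxonomy(new_id, category, label, actors = list(actors),
                       verbs = list(verb), objects = list(as_set(object)),
                       preps = list(as_set(prep)))
  new_taxonomy(dplyr::bind_rows(taxonomy, row))
}

#' Lint equivalence sets for spurious-match-prone short phrases
#'
#' Short object/prep equivalence-set members are the usual cause of a high
#' spurious-extraction rate: a 4-word-or-shorter phrase matches too much of
#' ordinary prose. The advised remedy is to lengthen the members of actions
#' that recur as spurious extractions to more than four words.
#'
#' @param taxonomy An `emat_taxonomy`.
#' @param min_words Warn on phrases with this many tokens or fewer
#'   (default 4).
#' @param roles Which sets to lint (default object and prep; verbs are short
#'   by nature).
#' @return A tibble with columns `action_id`, `label`, `role`, `phrase`,
#'   `n_tokens` — one row per flagged phrase, zero rows when clean.
#' @export
lint_equivalence_sets <- function(taxonomy, min_words = 4L,
                                  roles = c("object", "prep")) {
  stopifnot(min_words >= 1L)
  cols <- c(verb = "verbs", object = "objects", prep = "preps")[roles]
  out <- purrr::map_dfr(seq_len(nrow(taxonomy)), function(i) {
    purrr::map_dfr(names(cols), function(role) {
      ph <- taxonomy[[cols[[role]]]][[i]]
      nt <- lengths(strsplit(ph, " ", fixed = TRUE))
      tibble::tibble(action_id = taxonomy$action_id[i],
                     label = taxonomy$label[i], role = role,
                     phrase = ph, n_tokens = nt)[nt <= min_words, ]
    })
  })
  if (!nrow(out)) {
    out <- tibble::tibble(action_id = integer(), label = character(),
                          role = character(), phrase = character(),
                          n_tokens = integer())
  }
  out
}

#' Read a group or region lexicon
#'
#' One name per line; `#` comments and blank lines ignored; duplicates after
#' case-folding collapse to the first spelling seen.
#'
#' @param path Lexicon file path.
#' @return Character vector of names.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  x[!duplicated(tolower(x))]
}
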
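Package: ematr
Title: Taxonomy-Guided Extraction of Ecosystem Management Actions from News Stories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans machine-readable news "story" files for sentences whose
    m-word verbs, direct-object phrases, and prepositional phrases match an
    ecosystem management actions taxonomy (EMAT) under a modified phrasal
    overlap similarity measure, and emits dated, located, attributed action
    entities. Includes the similarity measure and its Levenshtein n-gram
    machinery, a rule-based shallow parser for verb/object/prepositional
    chunks, story-file readers with HTML stripping and a textual-content
    filter, software-assisted discovery of new equivalence-set members and
    actions, extraction-accuracy assessment against human benchmarks, and a
    synthetic story-file generator with manifest-tracked planted entities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
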
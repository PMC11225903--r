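# ematr

Taxonomy-guided extraction of ecosystem management actions from news
stories.

Researchers modelling human–wildlife systems (rhino poaching, cheetah
management, habitat encroachment) need structured event data assembled from
a noisy stream of scraped news stories. `ematr` scans delimited *story
files* for sentences whose m-word verbs, direct-object phrases, and
prepositional phrases match the equivalence sets of an **ecosystem
management actions taxonomy** (EMAT) — a catalogue of militaristic,
diplomatic, economic, ecosystem-directed anthropogenic, and ecological
actions — and emits **EMAT entities**: action occurrences tagged with date,
source, actor, target, and region. It also surfaces *learning candidates*
for growing the taxonomy, and scores extraction accuracy against human
benchmarks.

## The measure at the core

Phrases are compared with a modified phrasal overlap measure. With token
counts ordered so that N = |ph₁| ≤ |ph₂|,

    SIM(ph₁, ph₂) = (N / |ph₂|) · tanh[ (1/s) · Σₙ₌₁..N mₙ n² ]

where mₙ is the number of n-grams common to the phrases (two n-grams are
common when 1 − normalized Levenshtein distance > 0.99, absorbing
single-character scraping noise) and s = N(N+1)/2 counts aligned-start
n-gram pair formations. Identical single words score 1; every longer
identical phrase scores at least tanh(2) ≈ 0.9640, which is why the verb and
object match gates sit at 0.95. A sentence becomes an entity through a fixed
cascade: verb match (> 0.95) selects an action cluster; then the best
direct-object (> 0.95) and prepositional (> 0.8) matches within the cluster
decide — prepositional similarity above 0.8 wins outright, otherwise object
similarity must beat it. Near-misses with prepositional similarity in
[0.7, 0.8) feed the taxonomy-learning workflow.

## Worked example

Everything here is runnable as-is: a toy taxonomy and a 50-story synthetic
corpus with a ground-truth manifest stand in for a (copyrighted) scraped
corpus.

```r
library(ematr)
library(dplyr)

tax <- generate_toy_taxonomy(3, vocab_seed = 1)   # 15 actions, 5 categories
fx  <- generate_story_file(
  fixture_spec(n_stories = 50, entities_per_story = 2,
               junk_sentence_rate = 0.3, word_perturbation_rate = 0,
               html_fluff = TRUE, seed = 7),
  tax)

db <- parse_stories(fx$stories, tax, groups = fx$groups,
                    regions = fx$regions)
glance(db)
#> # A tibble: 1 × 5
#>   n_stories n_entities n_actions n_failed n_sentences
#>       <int>      <int>     <int>    <int>       <int>
#> 1        50        100        15        0         100

tidy(db) |> select(story_id, action_id, date, actor, target, rule) |> head(4)
#> # A tibble: 4 × 6
#>   story_id action_id date       actor            target            rule
#>      <int>     <int> <date>     <chr>            <chr>             <chr>
#> 1        1        10 2015-05-15 Mumube Authority Vatuviland Plains prep_accept
#> 2        1         3 2015-05-15 Lorogi Authority Manuraland Plains prep_accept
#> 3        2        10 2020-12-10 Zumamu Authority Zekaleland Plains prep_accept
#> 4        2         7 2020-12-10 Mumube Authority Debezaland Plains prep_accept
```

All 100 planted entities come back (100 entities over 50 stories, no parse
failures), each dated from its planted "Month D, YYYY" phrase, with the
actor group before the verb and the region after it. Scoring against the
generator's manifest as if it were a human benchmark:

```r
score_against_benchmark(tidy(db), fx$manifest |> select(story_id, action_id))
#> n_true = 100, r_correct = 1.00, r_spurious = 0.00
```

`r_correct` below 0.70 or `r_spurious` above 0.40 would add advisory flags
(and `autoplot()` marks them). The similarity decomposition behind any match
is inspectable:

```r
phrase_similarity("picked up", "picked up")
#> SIM = 0.9640  (N = 2, |ph2| = 2, s = 3, prefactor = 1.000)
#>   m_n: m_1=2, m_2=1
```

A thin command-line dispatcher over these functions (subcommands `concat`,
`extract`, `learn`, `assess`, `simulate`) is installed at
`inst/cli/emat.R`. The methods vignette
(`vignettes/emat-extraction.Rmd`) documents the cascade, threshold
decisions, and generator assumptions.

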
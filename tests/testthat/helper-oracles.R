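# Independent oracles used to cross-check the implementation. These are
# deliberately written as plain, unoptimized re-derivations.

# memoized naive recursion for edit distance
lev_recursive <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (substr(a, i, i) == substr(b, j, j)) 0L else 1L
    r <- min(f(i - 1L, j) + 1L, f(i, j - 1L) + 1L, f(i - 1L, j - 1L) + cost)
    memo[[key]] <- r
    r
  }
  f(nchar(a), nchar(b))
}

# direct enumeration of every n-gram pair, greedy one-to-one consumption,
# then the tanh formula evaluated literally
sim_oracle <- function(ph1, ph2, thr = 0.99) {
  t1 <- strsplit(tolower(ph1), "\\s+")[[1]]
  t2 <- strsplit(tolower(ph2), "\\s+")[[1]]
  if (length(t1) > length(t2)) { tmp <- t1; t1 <- t2; t2 <- tmp }
  N <- length(t1); L2 <- length(t2)
  if (N == 1L && L2 == 1L) {
    return(1 - utils::adist(t1, t2)[1, 1] / max(nchar(t1), nchar(t2)))
  }
  grams <- function(t, n) {
    sapply(seq_len(length(t) - n + 1L),
           function(i) paste(t[i:(i + n - 1L)], collapse = " "))
  }
  total <- 0
  for (n in seq_len(N)) {
    g1 <- grams(t1, n)
    if (n > L2) break
    g2 <- grams(t2, n)
    used <- rep(FALSE, length(g2))
    m <- 0L
    for (x in g1) {
      for (j in seq_along(g2)) {
        if (used[j]) next
        sim <- 1 - utils::adist(x, g2[j])[1, 1] / max(nchar(x), nchar(g2[j]))
        if (sim > thr) { used[j] <- TRUE; m <- m + 1L; break }
      }
    }
    total <- total + m * n^2
  }
  s <- N * (N + 1) / 2
  (N / L2) * tanh(total / s)
}

# literal transcription of the extraction cascade, step by step, sharing
# only the similarity primitive with the implementation
cascade_oracle <- function(parse, tax, cfg = extraction_config()) {
  # (i) best verb over every span and every verb-set member; cluster = all
  # actions with a member above the gate for that best span
  span_best <- rep(0, nrow(parse$verbs))
  for (k in seq_len(nrow(parse$verbs))) {
    for (i in seq_len(nrow(tax))) {
      for (mem in tax$verbs[[i]]) {
        sc <- phrase_similarity(parse$verbs$verb[k], mem, cfg$sim)$score
        if (sc > span_best[k]) span_best[k] <- sc
      }
    }
  }
  if (!length(span_best) || max(span_best) <= cfg$verb_gate) {
    return(list(accepted = FALSE, action_id = NA_integer_))  # (ii)
  }
  k <- which.max(span_best)
  verb <- parse$verbs$verb[k]
  cluster <- integer()
  for (i in order(tax$action_id)) {
    sc <- max(vapply(tax$verbs[[i]],
                     function(m) phrase_similarity(verb, m, cfg$sim)$score,
                     numeric(1)))
    if (sc > cfg$verb_gate) cluster <- c(cluster, tax$action_id[i])
  }
  if (!length(cluster)) return(list(accepted = FALSE, action_id = NA_integer_))

  SIMD <- 0; SIMP <- 0                                       # (iii)
  actionD <- NA_integer_; actionP <- NA_integer_
  objs <- parse$verbs$object
  objs <- objs[!is.na(objs)]
  for (id in sort(cluster)) {                                # (iv)
    row <- match(id, tax$action_id)
    for (cand in objs) {
      for (mem in tax$objects[[row]]) {
        sc <- phrase_similarity(cand, mem, cfg$sim)$score
        if (sc > cfg$object_gate && sc > SIMD) { SIMD <- sc; actionD <- id }
      }
    }
  }
  for (id in sort(cluster)) {                                # (v)
    row <- match(id, tax$action_id)
    for (cand in parse$preps$phrase) {
      for (mem in tax$preps[[row]]) {
        sc <- phrase_similarity(cand, mem, cfg$sim)$score
        if (sc > cfg$prep_gate && sc > SIMP) { SIMP <- sc; actionP <- id }
      }
    }
  }
  if (is.na(actionD) && is.na(actionP)) {                    # (vi)
    return(list(accepted = FALSE, action_id = NA_integer_))
  }
  if (SIMP > cfg$prep_accept) {                              # (vii)
    return(list(accepted = TRUE, action_id = actionP))
  }
  if (SIMD > SIMP) {                                         # (viii)
    return(list(accepted = TRUE, action_id = actionD))
  }
  list(accepted = FALSE, action_id = NA_integer_)
}
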
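# Independent oracles used across the suite.

# Naive exponential recursion for the Levenshtein distance: no table, no
# memoisation; only usable for short strings.
naive_edit_distance <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- if (substr(a, 1L, 1L) == substr(b, 1L, 1L)) 0L else 1L
  ta <- substring(a, 2L)
  tb <- substring(b, 2L)
  min(naive_edit_distance(ta, tb) + cost,
      naive_edit_distance(ta, b) + 1L,
      naive_edit_distance(a, tb) + 1L)
}

random_dna <- function(n, min_len = 1L, max_len = 8L) {
  lens <- min_len:max_len
  vapply(seq_len(n), function(i) {
    len <- lens[sample.int(length(lens), 1L)]
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

random_tag_set <- function(n_tags = 5L, len = 6L) {
  seqs <- unique(random_dna(n_tags * 3L, len, len))[seq_len(n_tags)]
  tag_set(seqs, names = paste0("t", seq_len(n_tags)))
}

# Exact maximum conforming-subset size by exhaustive subset enumeration
# (feasible for <= ~15 tags).
brute_force_max_conforming <- function(seqs, d) {
  n <- length(seqs)
  m <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) edit_distance(seqs[i], seqs[j])))
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1L) {
      sub <- m[idx, idx]
      ok <- min(sub[upper.tri(sub)]) >= d
    }
    if (ok) best <- length(idx)
  }
  best
}

# Plain greedy lexicode over a pool in its given order: keep a candidate
# iff it is >= d from everything already kept.
plain_lexicode <- function(pool, d) {
  kept <- character(0)
  for (cand in pool) {
    if (length(kept) == 0L ||
        all(edit_distance(rep(cand, length(kept)), kept) >= d))
      kept <- c(kept, cand)
  }
  kept
}

# TRUE iff no filtered candidate outside the set could be added without
# breaking the minimum distance.
is_maximal_design <- function(set, spec) {
  pool <- enumerate_candidates(spec$tag_length)
  pool <- pool[passes_filters(pool, spec)]
  outside <- setdiff(pool, set$sequences)
  members <- unname(set$sequences)
  for (cand in outside) {
    d_min <- min(edit_distance(rep(cand, length(members)), members))
    if (d_min >= spec$min_distance) return(FALSE)
  }
  TRUE
}

# Exact maximum independent-set size of the conflict graph (pairs closer
# than d conflict), via igraph's exact solver.
igraph_max_code_size <- function(pool, d) {
  m <- outer(seq_along(pool), seq_along(pool),
             Vectorize(function(i, j) edit_distance(pool[i], pool[j])))
  conflict <- m < d
  diag(conflict) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(conflict, mode = "undirected")
  igraph::independence_number(g)
}
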
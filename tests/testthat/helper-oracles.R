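# Independent brute-force oracles used to cross-check the implementation.

# Pairwise intersection histogram by direct set intersection.
brute_pair_hist <- function(design) {
  sigs <- signatures(design)
  n <- design$n
  t <- integer(0)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      t <- c(t, length(intersect(sigs[a, ], sigs[b, ])))
    }
  }
  as.vector(table(factor(t, levels = 0:design$gamma)))
}

# Triple union-deficit histogram by direct enumeration.
brute_triple_hist <- function(design) {
  sigs <- signatures(design)
  n <- design$n
  L <- design$layers
  x <- integer(0)
  for (a in seq_len(n - 2)) {
    for (b in (a + 1):(n - 1)) {
      for (c in (b + 1):n) {
        x <- c(x, 3 * L - length(unique(c(sigs[a, ], sigs[b, ], sigs[c, ]))))
      }
    }
  }
  as.vector(table(factor(x, levels = 0:(3 * design$gamma))))
}

# Exhaustive re-implementation of the k-mer decision tree: the same band
# structure and drop rule, but searching all 1-, 2- and 3-clone unions by
# brute force (set operations, no candidate pruning, no bitmasks).
brute_classify <- function(counts, design, source_pool) {
  L <- design$layers
  G <- design$gamma
  n <- design$n
  sigs <- signatures(design)
  support <- which(counts > 0) - 1L
  w <- length(support)
  stopifnot(counts[source_pool + 1] > 0)

  drop_smallest <- function(S, d) {
    droppable <- S[S != source_pool]
    ord <- droppable[order(counts[droppable + 1], droppable)]
    setdiff(S, ord[seq_len(min(d, length(ord)))])
  }
  match_single <- function(S) {
    if (length(S) == L) {
      for (i in seq_len(n)) {
        if (setequal(sigs[i, ], S))
          return(list(status = "assigned", clones = i - 1L))
      }
    }
    list(status = "unmatched", clones = integer(0))
  }
  match_union <- function(S, arity) {
    combos <- combn(n, arity)
    for (j in seq_len(ncol(combos))) {
      u <- unique(as.vector(sigs[combos[, j], ]))
      if (setequal(u, S))
        return(list(status = "assigned", clones = combos[, j] - 1L))
    }
    list(status = "unmatched", clones = integer(0))
  }

  if (w < L) return(list(status = "error_discard", clones = integer(0)))
  if (w == L) return(match_single(support))
  if (w < 2 * L - 2 * G) return(match_single(drop_smallest(support, w - L)))
  if (w <= 2 * L) return(match_union(support, 2))
  if (w < 3 * L - 3 * G) return(match_union(drop_smallest(support, w - 2 * L), 2))
  if (w <= 3 * L) return(match_union(support, 3))
  list(status = "repeat_discard", clones = integer(0))
}

# Exhaustive error-minimising decoder over all clone subsets of size <= max_set.
brute_decode <- function(S, design, max_set = 3, cap = 3) {
  if (length(S) == 0) {
    return(list(clones = integer(0), error_count = NA_integer_,
                decodable = FALSE))
  }
  sigs <- signatures(design)
  n <- design$n
  best_e <- Inf
  best <- integer(0)
  for (sz in seq_len(max_set)) {
    combos <- combn(n, sz)
    for (j in seq_len(ncol(combos))) {
      u <- unique(as.vector(sigs[combos[, j], , drop = FALSE]))
      e <- length(setdiff(u, S)) + length(setdiff(S, u))
      if (e < best_e) {
        best_e <- e
        best <- combos[, j] - 1L
      }
    }
  }
  if (best_e > cap) {
    list(clones = integer(0), error_count = as.integer(best_e), decodable = FALSE)
  } else {
    list(clones = sort(best), error_count = as.integer(best_e), decodable = TRUE)
  }
}

# Worst-case guaranteed exact run: enumerate every placement of at most mm
# mismatches, take the longest run of each, report the minimum.
brute_guaranteed_run <- function(len, mm) {
  worst <- len
  placements <- list(integer(0))
  for (m in seq_len(mm)) {
    if (m > 0) placements <- c(placements, combn(len, m, simplify = FALSE))
  }
  for (pos in placements) {
    runs <- diff(c(0L, sort(pos), len + 1L)) - 1L
    worst <- min(worst, max(runs))
  }
  worst
}
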
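test_that("STD construction reproduces the full-scale design dimensions", {
  d <- std_design(13, 7, 2, 2197)
  expect_equal(d$n_pools, 91)
  expect_equal(d$n, 13^3)
  sig <- signatures(d)
  expect_equal(dim(sig), c(2197, 7))
  # one pool per layer, in the layer's range
  for (j in 0:6) expect_true(all(sig[, j + 1] >= j * 13 & sig[, j + 1] < (j + 1) * 13))
  # full capacity: every pool holds exactly P^gamma members
  expect_true(all(lengths(pool_members(d)) == 169))
})

test_that("the layer polynomial places items where expected on a tiny design", {
  d <- std_design(3, 3, 1, 9)
  expect_identical(signatures(d)[1, ], c(0L, 3L, 6L))  # digits (0,0): zero polynomial
  expect_identical(signatures(d)[5, ], c(1L, 5L, 6L))  # item 4, digits (1,1)
  # membership is the exact transpose of signatures
  memb <- pool_members(d)
  for (p in 0:(d$n_pools - 1)) {
    for (i in memb[[p + 1]]) expect_true(p %in% signatures(d)[i + 1, ])
  }
  # construction is a pure function of the parameters
  expect_identical(d, std_design(3, 3, 1, 9))
})

test_that("invalid design parameters are rejected by name", {
  expect_error(std_design(4, 2, 1, 4), "not prime")
  expect_error(std_design(3, 4, 1, 9), "L <= P")
  expect_error(std_design(3, 3, 1, 10), "P\\^\\(gamma\\+1\\)")
  expect_error(std_design(3, 3, 0, 3), "gamma")
})

test_that("pairwise sharing matches the brute-force oracle and stays <= gamma", {
  d <- std_design(3, 3, 1, 9)
  ps <- pair_sharing(d)
  expect_equal(ps$pairs, brute_pair_hist(d))
  expect_equal(sum(ps$pairs), choose(9, 2))
  expect_equal(sum(ps$pct), 100)

  d2 <- std_design(5, 4, 1, 25)
  ps2 <- pair_sharing(d2)
  expect_equal(ps2$pairs, brute_pair_hist(d2))
  expect_true(all(lengths(pool_members(d2)) == 5))
})

test_that("single-item designs have no pair statistics", {
  d <- std_design(3, 3, 1, 1)
  expect_equal(nrow(pair_sharing(d)), 0)
  expect_error(min_signature_distance(d), "n >= 2")
  expect_error(triple_sharing(d), "n >= 3")
})

test_that("triple sharing matches exhaustive enumeration and is reproducible", {
  d <- std_design(3, 3, 1, 9)
  ts <- triple_sharing(d, all = TRUE)
  expect_equal(ts$triples, brute_triple_hist(d))
  expect_equal(sum(ts$triples), choose(9, 3))
  expect_equal(sum(ts$pct), 100)
  # sampling: reproducible for a fixed seed, all mass within [0, 3*gamma]
  s1 <- triple_sharing(d, n_triples = 50, seed = 11)
  s2 <- triple_sharing(d, n_triples = 50, seed = 11)
  expect_identical(s1, s2)
  expect_equal(sum(s1$triples), 50)
})

test_that("three pairwise-disjoint signatures have zero shared pools", {
  d <- std_design(13, 7, 2, 2197)
  sig <- signatures(d)
  # items 0, 1, 2 differ only in the constant digit: layer pools (i0 + i1 j +
  # i2 j^2) mod P differ in every layer
  expect_equal(length(intersect(sig[1, ], sig[2, ])), 0)
  expect_equal(3 * 7 - length(unique(c(sig[1, ], sig[2, ], sig[3, ]))), 0)
})

test_that("decodability follows floor((L-1)/gamma) and verifies exhaustively", {
  expect_equal(decodability(std_design(13, 7, 2, 2197)), 3)
  expect_equal(decodability(std_design(5, 3, 2, 125)), 1)  # L = gamma + 1
  d <- std_design(5, 4, 1, 25)
  expect_equal(decodability(d), 3)
  # unions of up to 3 signatures are pairwise distinct
  sigs <- signatures(d)
  keys <- character(0)
  for (sz in 1:3) {
    combos <- combn(25, sz)
    keys <- c(keys, apply(combos, 2, function(ix) {
      paste(sort(unique(as.vector(sigs[ix, , drop = FALSE]))), collapse = ",")
    }))
  }
  expect_false(any(duplicated(keys)))
})

test_that("minimum signature distance matches brute force and its bound", {
  d <- std_design(3, 3, 1, 9)
  sigs <- signatures(d)
  dists <- c()
  for (a in 1:8) for (b in (a + 1):9) {
    dists <- c(dists, length(setdiff(sigs[a, ], sigs[b, ])) +
                      length(setdiff(sigs[b, ], sigs[a, ])))
  }
  expect_equal(min_signature_distance(d), min(dists))
  expect_gte(min_signature_distance(d), 2 * (d$layers - d$gamma))
  # two items sharing no pool at L = 7: distance 14
  d2 <- std_design(13, 7, 2, 2)
  expect_equal(min_signature_distance(d2), 14)
})

test_that("pool manifests round-trip and reject malformed input", {
  d <- std_design(5, 4, 1, 25)
  f <- tempfile(fileext = ".tsv")
  write_pool_manifest(d, f)
  d2 <- read_pool_manifest(f)
  expect_identical(signatures(d2), signatures(d))
  expect_identical(d2$clone_ids, d$clone_ids)
  expect_equal(d2$p, 5)
  expect_equal(d2$gamma, 1)

  # hand-written 9-clone manifest for (3,3,1) passes all invariants
  d3 <- std_design(3, 3, 1, 9)
  f3 <- tempfile(fileext = ".tsv")
  lines <- c("# poolkit design P=3 L=3 gamma=1",
             paste("clone_id", "pool_layer_0", "pool_layer_1", "pool_layer_2",
                   sep = "\t"),
             sprintf("bac%d\t%d\t%d\t%d", 0:8, signatures(d3)[, 1],
                     signatures(d3)[, 2], signatures(d3)[, 3]))
  writeLines(lines, f3)
  d4 <- read_pool_manifest(f3)
  expect_identical(unname(signatures(d4)), unname(signatures(d3)))
  expect_true(all(pair_sharing(d4)$shared <= d4$gamma | pair_sharing(d4)$pairs == 0))

  # out-of-range pool index is rejected
  bad <- sub("^bac0\t0", "bac0\t9", lines)
  writeLines(bad, f3)
  expect_error(read_pool_manifest(f3), "outside")
  # unknown header is rejected
  bad2 <- lines
  bad2[2] <- "clone\tp0\tp1\tp2"
  writeLines(bad2, f3)
  expect_error(read_pool_manifest(f3), "header")
  # duplicate ids are rejected
  bad3 <- lines
  bad3[4] <- sub("^bac1", "bac0", bad3[4])
  writeLines(bad3, f3)
  expect_error(read_pool_manifest(f3), "unique")
})
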
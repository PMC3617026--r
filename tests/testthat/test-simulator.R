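test_that("genome simulation honours length, GC and determinism", {
  g1 <- sim_genome(2e4, gc = 0.44, seed = 1)
  g2 <- sim_genome(2e4, gc = 0.44, seed = 1)
  expect_equal(nchar(g1), 2e4)
  expect_identical(as.character(g1), as.character(g2))
  gc <- mean(strsplit(as.character(g1), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.44), 0.02)
})

test_that("planted repeat families are recoverable by scanning", {
  g <- sim_genome(3e4, repeats = data.frame(unit_length = 300, copies = 20,
                                            divergence = 0.05), seed = 5)
  unit <- attr(g, "repeat_units")[1]
  hits <- Biostrings::matchPattern(unit, Biostrings::DNAString(as.character(g)),
                                   max.mismatch = 30)  # >= 90% identity
  expect_gte(length(hits), 20)
  # placements recorded in the provenance are mutated copies of the unit
  cp <- attr(g, "repeat_copies")
  expect_equal(nrow(cp), 20)
  for (i in seq_len(nrow(cp))) {
    copy <- substr(g, cp$start[i] + 1, cp$end[i])
    mism <- sum(strsplit(copy, "")[[1]] != strsplit(unit, "")[[1]])
    expect_lte(mism / 300, 0.15)
  }
})

test_that("infeasible repeat placement errors", {
  expect_error(sim_genome(1000, repeats = data.frame(unit_length = 400,
                                                     copies = 5,
                                                     divergence = 0),
                          seed = 1),
               "infeasible repeat placement")
})

test_that("clone layout tiles deterministically with requested overlaps", {
  lay <- sim_clone_layout(1e6, 9, 120000, 0, 10000, 0, seed = 1)
  expect_equal(nrow(lay), 9)
  expect_equal(lay$end - lay$start, rep(120000, 9))
  expect_equal(lay$end[-9] - lay$start[-1], rep(10000, 8))  # consecutive overlap
  expect_equal(lay$end[9], 1e6)

  disj <- sim_clone_layout(1e6, 8, 100000, 0, 0, 0, seed = 1)
  expect_true(all(disj$start[-1] >= disj$end[-8]))
  expect_error(sim_clone_layout(1e5, 9, 120000, 0, 10000, 0), "infeasible")
})

test_that("random layouts satisfy the coverage and bound invariants", {
  for (s in 1:100) {
    lay <- sim_clone_layout(2e6, 10, 5e4, 5e3, 1e4, 3e3, seed = s)
    expect_true(all(lay$start >= 0))
    expect_true(all(lay$start < lay$end))
    expect_true(all(lay$end <= 2e6))
    # no base covered by more than 3 clones
    if (nrow(lay) > 3) {
      expect_true(all(lay$start[-(1:3)] >= lay$end[seq_len(nrow(lay) - 3)]))
    }
  }
})

test_that("error-free reads are exact clone substrings in the right pools", {
  d <- std_design(3, 3, 1, 1)   # single clone, pools {0, 3, 6}
  g <- sim_genome(5000, seed = 2)
  lay <- sim_clone_layout(5000, 1, 5000, 0, 0, 0, seed = 2)
  dir <- tempfile()
  w <- capture_warnings(
    sim <- sim_pool_reads(d, lay, g, dir, read_length = 100, insert_mean = 300,
                          error_rate = 0, pairs_per_pool = 10, seed = 3))
  expect_true(any(grepl("no usable clones", w)))
  clone <- substr(g, 1, 5000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(clone)))
  for (p in c(0, 3, 6)) {
    fq <- read_fastq(sim$files$r1[p + 1])
    expect_equal(length(fq$seq), 10)
    expect_true(all(vapply(fq$seq, function(s) grepl(s, clone, fixed = TRUE),
                           logical(1))))
    fq2 <- read_fastq(sim$files$r2[p + 1])
    expect_true(all(vapply(fq2$seq, function(s) grepl(s, rc, fixed = TRUE),
                           logical(1))))
  }
  # empty pools got empty files
  expect_equal(length(read_fastq(sim$files$r1[2])$seq), 0)
})

test_that("every simulated read's source clone is a member of its pool", {
  d <- std_design(3, 3, 1, 9)
  g <- sim_genome(9 * 4000, seed = 4)
  lay <- sim_clone_layout(nchar(g), 9, 4000, 0, 0, 0, seed = 4)
  dir <- tempfile()
  sim <- sim_pool_reads(d, lay, g, dir, read_length = 100, insert_mean = 300,
                        error_rate = 0, depth_per_pool = 3, seed = 5)
  truth <- read_truth(sim$truth)
  memb <- pool_members(d)
  item <- match(truth$clone_id, lay$clone_id) - 1L
  ok <- vapply(seq_len(nrow(truth)), function(i) {
    item[i] %in% memb[[truth$pool[i] + 1]]
  }, logical(1))
  expect_true(all(ok))
  # depth accounting: total bases per pool within 1% of the requested budget
  pool_lens <- vapply(memb, function(m) sum(lay$end[m + 1] - lay$start[m + 1]),
                      numeric(1))
  for (p in 0:8) {
    bases <- sum(nchar(read_fastq(sim$files$r1[p + 1])$seq)) +
             sum(nchar(read_fastq(sim$files$r2[p + 1])$seq))
    expect_lt(abs(bases - 3 * pool_lens[p + 1]) / (3 * pool_lens[p + 1]), 0.01)
  }
})

test_that("the observed substitution rate matches the error model", {
  d <- std_design(3, 3, 1, 9)
  g <- sim_genome(9 * 4000, seed = 6)
  lay <- sim_clone_layout(nchar(g), 9, 4000, 0, 0, 0, seed = 6)
  dir <- tempfile()
  sim <- sim_pool_reads(d, lay, g, dir, read_length = 104, insert_mean = 327,
                        error_rate = 0.01, depth_per_pool = 5, seed = 7)
  truth <- read_truth(sim$truth)
  clone_seq <- substring(g, lay$start + 1, lay$end)
  names(clone_seq) <- lay$clone_id
  mism <- 0; tot <- 0
  for (p in 0:8) {
    for (mate in 1:2) {
      fq <- read_fastq(sim$files[[c("r1", "r2")[mate]]][p + 1])
      m <- match(fq$id, truth$read_id)
      expect_false(anyNA(m))
      expected <- substr(clone_seq[truth$clone_id[m]], truth$start[m] + 1,
                         truth$end[m])
      if (mate == 2) {
        expected <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(expected)))
      }
      a <- strsplit(fq$seq, ""); b <- strsplit(expected, "")
      mism <- mism + sum(mapply(function(x, y) sum(x != y), a, b))
      tot <- tot + sum(nchar(fq$seq))
    }
  }
  expect_lt(abs(mism / tot - 0.01), 0.002)
})

test_that("simulation is byte-identical for a fixed seed", {
  d <- std_design(3, 3, 1, 9)
  g <- sim_genome(9 * 3000, seed = 8)
  lay <- sim_clone_layout(nchar(g), 9, 3000, 0, 0, 0, seed = 8)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- sim_pool_reads(d, lay, g, d1, read_length = 80, insert_mean = 200,
                       error_rate = 0.01, depth_per_pool = 2, seed = 99)
  s2 <- sim_pool_reads(d, lay, g, d2, read_length = 80, insert_mean = 200,
                       error_rate = 0.01, depth_per_pool = 2, seed = 99)
  for (p in 0:8) {
    expect_identical(readLines(s1$files$r1[p + 1]), readLines(s2$files$r1[p + 1]))
    expect_identical(readLines(s1$files$r2[p + 1]), readLines(s2$files$r2[p + 1]))
  }
  expect_identical(readLines(s1$truth), readLines(s2$truth))
})

test_that("contaminant read pairs are flagged in the truth table", {
  d <- std_design(3, 3, 1, 9)
  g <- sim_genome(9 * 3000, seed = 9)
  lay <- sim_clone_layout(nchar(g), 9, 3000, 0, 0, 0, seed = 9)
  contam <- sim_genome(4000, seed = 10)
  dir <- tempfile()
  sim <- sim_pool_reads(d, lay, g, dir, read_length = 80, insert_mean = 200,
                        error_rate = 0, pairs_per_pool = 50,
                        contaminant = as.character(contam),
                        contaminant_fraction = 0.4, seed = 11)
  truth <- read_truth(sim$truth)
  expect_equal(mean(truth$is_contaminant), 0.4, tolerance = 1e-9)
  expect_true(all(truth$clone_id[truth$is_contaminant == 1] == "contaminant"))
  # contaminant reads come from the contaminant sequence
  sel <- truth[truth$is_contaminant == 1 & grepl("/1$", truth$read_id), ][1:5, ]
  fq <- read_fastq(sim$files$r1[sel$pool[1] + 1])
  s <- fq$seq[match(sel$read_id, fq$id)]
  expect_true(all(vapply(s, function(x) {
    grepl(x, as.character(contam), fixed = TRUE)
  }, logical(1))))
})

test_that("clones shorter than the insert are skipped with a warning", {
  d <- std_design(3, 3, 1, 2)
  g <- sim_genome(4200, seed = 12)
  lay <- data.frame(clone_id = c("clone_0", "clone_1"),
                    start = c(0L, 4000L), end = c(4000L, 4150L))
  class(lay) <- c("clone_layout", "data.frame")
  dir <- tempfile()
  w <- capture_warnings(
    sim <- sim_pool_reads(d, lay, g, dir, read_length = 100, insert_mean = 300,
                          error_rate = 0, pairs_per_pool = 5, seed = 13))
  expect_true(any(grepl("shorter than the mean insert", w)))
  truth <- read_truth(sim$truth)
  expect_true(all(truth$clone_id == "clone_0"))
})
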
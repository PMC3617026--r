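test_that("candidate clones equal the brute-force subset filter", {
  d <- std_design(3, 3, 1, 9)
  sigs <- signatures(d)
  expect_equal(candidate_clones(sigs[1, ], d), 0L)
  expect_equal(candidate_clones(integer(0), d), integer(0))
  set.seed(7)
  for (i in 1:50) {
    support <- sort(sample(0:8, sample(0:9, 1)))
    brute <- which(vapply(1:9, function(j) all(sigs[j, ] %in% support),
                          logical(1))) - 1L
    expect_equal(candidate_clones(support, d), brute)
  }
})

test_that("low-support k-mers are discarded as likely errors", {
  d <- std_design(13, 7, 2, 50)
  counts <- integer(91)
  counts[c(1, 14, 27)] <- 5  # w = 3 < L = 7
  r <- classify_kmer(counts, d, source_pool = 0)
  expect_equal(r$status, "error_discard")
})

test_that("a support equal to one signature is assigned to that clone", {
  d <- std_design(13, 7, 2, 50)
  counts <- integer(91)
  counts[signatures(d)[8, ] + 1] <- 3
  r <- classify_kmer(counts, d, source_pool = signatures(d)[8, 1])
  expect_equal(r$status, "assigned")
  expect_equal(r$clones, 7L)
  expect_equal(sort(r$matched_support), sort(signatures(d)[8, ]))
})

test_that("classification agrees with the exhaustive union search on every support", {
  d <- std_design(3, 3, 1, 9)
  supports <- expand.grid(rep(list(c(FALSE, TRUE)), 9))
  for (i in seq_len(nrow(supports))) {
    S <- which(unlist(supports[i, ])) - 1L
    if (length(S) == 0) next
    src <- S[1]
    # uniform counts (ties everywhere) and a graded count profile
    for (profile in 1:2) {
      counts <- integer(9)
      counts[S + 1] <- if (profile == 1) 1L else (S %% 3L) + 1L
      got <- classify_kmer(counts, d, src)
      want <- brute_classify(counts, d, src)
      expect_equal(got$status, want$status,
                   info = paste("support", paste(S, collapse = ","), "profile", profile))
      expect_equal(sort(got$clones), sort(want$clones),
                   info = paste("support", paste(S, collapse = ",")))
    }
  }
})

test_that("a zero count in the source pool violates the contract", {
  d <- std_design(3, 3, 1, 9)
  counts <- integer(9)
  counts[signatures(d)[1, ] + 1] <- 1
  expect_error(classify_kmer(counts, d, source_pool = 1), "contract violation")
})

test_that("reads are assigned to the union of their k-mers' clone sets", {
  d <- std_design(3, 3, 1, 9)
  set.seed(8)
  shared <- random_seq(30)                 # overlap between clones 0 and 1
  unique_parts <- replicate(9, random_seq(60))
  clone_seq <- unique_parts
  clone_seq[1] <- paste0(unique_parts[1], shared)
  clone_seq[2] <- paste0(shared, unique_parts[2])
  memb <- pool_members(d)
  pools <- lapply(memb, function(m) clone_seq[m + 1])
  tab <- kmer_count_table(pools, k = 11)

  # read entirely within clone 0's unique part
  r1 <- deconvolve_read(substr(clone_seq[1], 10, 50), tab, d, source_pool = 0)
  expect_equal(r1$status, "deconvoluted")
  expect_equal(r1$clones, "clone_0")
  expect_equal(r1$support_w, d$layers)

  # read straddling the junction: k-mers assigned {0} and {0,1} -> {0,1}
  r2 <- deconvolve_read(substr(clone_seq[1], 45, 85), tab, d, source_pool = 0)
  expect_equal(r2$status, "deconvoluted")
  expect_equal(sort(r2$clones), c("clone_0", "clone_1"))

  # chimeric read spanning four clones is non-deconvolutable
  chimera <- paste0(substr(unique_parts[3], 1, 15), substr(unique_parts[4], 1, 15),
                    substr(unique_parts[5], 1, 15), substr(unique_parts[6], 1, 15))
  r3 <- deconvolve_read(chimera, tab, d, source_pool = signatures(d)[3, 1])
  expect_equal(r3$status, "non_deconvolutable")
  expect_equal(r3$reason, "too_many_clones")

  # a read with no k-mer in the table has no assigned k-mers
  r4 <- deconvolve_read(strrep("A", 20), tab, d, source_pool = 0)
  expect_equal(r4$status, "non_deconvolutable")
  expect_equal(r4$reason, "no_assigned_kmers")
})

test_that("pool deconvolution accounts for every read across output files", {
  d <- std_design(3, 3, 1, 9)
  g <- sim_genome(9 * 4000 - 8 * 500, seed = 14)
  lay <- sim_clone_layout(nchar(g), 9, 4000, 0, 500, 0, seed = 14)
  dir <- tempfile(); outdir <- tempfile()
  pipe <- run_pipeline(d, lay, as.character(g), dir, k = 26, outdir = outdir,
                       read_length = 100, insert_mean = 300, error_rate = 0,
                       depth_per_pool = 4, seed = 15)
  res <- pipe$result
  a <- res$assignments

  # summary counts recount from the assignment table
  for (p in 0:8) {
    ap <- a[a$pool == p, ]
    s <- res$summary[res$summary$pool == p, ]
    expect_equal(s$total, nrow(ap))
    expect_equal(s$to_1, sum(ap$n_clones == 1))
    expect_equal(s$to_2, sum(ap$n_clones == 2))
    expect_equal(s$to_3, sum(ap$n_clones == 3))
  }

  # per-clone FASTQ files hold each deconvoluted read once per assigned clone
  ok <- a$status == "deconvoluted"
  expected_per_clone <- table(unlist(strsplit(a$clones[ok], ",")))
  for (cid in names(expected_per_clone)) {
    fq <- read_fastq(file.path(outdir, paste0(cid, ".fastq")))
    expect_equal(length(fq$id), as.integer(expected_per_clone[[cid]]))
    expect_false(anyDuplicated(fq$id) > 0)
  }
  nd <- file.path(outdir, "non_deconvolutable.fastq")
  n_nd <- if (file.exists(nd)) length(read_fastq(nd)$id) else 0
  expect_equal(n_nd, sum(!ok))

  # read signature histogram totals the input reads
  h <- read_signature_histogram(res)
  expect_equal(sum(h$reads), nrow(a))
})

test_that("error-free disjoint clones deconvolute perfectly to their source", {
  # depth must be high enough that every k-mer position is covered in all of
  # its clone's pools; at 20x the chance of a coverage gap is negligible
  d <- std_design(3, 3, 1, 9)
  g <- sim_genome(9 * 4000, seed = 16)
  lay <- sim_clone_layout(nchar(g), 9, 4000, 0, 0, 0, seed = 16)
  pipe <- run_pipeline(d, lay, as.character(g), tempfile(), k = 26,
                       read_length = 100, insert_mean = 300, error_rate = 0,
                       depth_per_pool = 20, seed = 17)
  a <- pipe$result$assignments
  truth <- pipe$truth
  expect_equal(deconvolution_rate(pipe$result), 1)
  src <- truth$clone_id[match(a$read_id, truth$read_id)]
  hit <- mapply(function(cl, s) s %in% strsplit(cl, ",")[[1]], a$clones, src)
  expect_true(all(hit))
  # all read signatures sit at w = L
  expect_equal(unique(a$support_w), d$layers)
})

test_that("deconvolution output is invariant to which pools are processed", {
  d <- std_design(3, 3, 1, 9)
  g <- sim_genome(9 * 3000, seed = 18)
  lay <- sim_clone_layout(nchar(g), 9, 3000, 0, 0, 0, seed = 18)
  pipe <- run_pipeline(d, lay, as.character(g), tempfile(), k = 26,
                       read_length = 80, insert_mean = 250, error_rate = 0.01,
                       depth_per_pool = 3, seed = 19)
  # re-running a subset of pools against the same table reproduces those rows
  sub <- deconvolve_pools(pipe$files[c(2, 5)], pipe$table, d,
                          pool_indices = c(1L, 4L))
  full <- pipe$result$assignments
  expect_equal(sub$assignments$status,
               full$status[full$pool %in% c(1, 4)])
  expect_equal(sub$assignments$clones,
               full$clones[full$pool %in% c(1, 4)])
})
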
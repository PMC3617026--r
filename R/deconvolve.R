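# Read-to-clone deconvolution: match k-mer count-vector supports against
# unions of clone signatures, then assign each read to the union of its
# k-mers' clone sets.

kmer_status_labels <- c("error_discard", "assigned", "unmatched", "repeat_discard")

#' Clones whose signature is contained in a pool set
#'
#' @param support integer vector of 0-based pool indices.
#' @param design a `pooling_design`.
#' @return integer vector of 0-based item indices (clones with
#'   signature a subset of `support`).
#' @export
candidate_clones <- function(support, design) {
  stopifnot(inherits(design, "pooling_design"))
  if (length(support) == 0) return(integer(0))
  if (any(support < 0 | support >= design$n_pools))
    stop("support pool index out of [0, L*P)")
  inset <- matrix(design$signatures %in% support, nrow = design$n)
  which(rowSums(inset) == design$layers) - 1L
}

#' Classify one k-mer count vector
#'
#' Applies the band-structured decision tree at the k-mer level of the
#' deconvolution algorithm. With w the number of positive pools:
#' w < L is discarded as a likely sequencing error; w = L must equal one clone
#' signature; L < w < 2L-2\eqn{\Gamma} drops the w-L smallest counts (never
#' the source pool's; ties drop the lower pool index) and re-tests; within
#' \[2L-2\eqn{\Gamma}, 2L\] the support must equal a union of two clone
#' signatures; up to 2L it is reduced and re-tested as a pair; within
#' \[3L-3\eqn{\Gamma}, 3L\] a union of three; and w > 3L is discarded as
#' highly repetitive. Bands are tried strictly in this order; a failed match
#' is `unmatched`.
#'
#' @param counts integer vector of per-pool counts (length `n_pools`).
#' @param design a `pooling_design`.
#' @param source_pool 0-based index of the pool the read came from; its entry
#'   must be positive (that pool genuinely contains the k-mer).
#' @return list with `status` (one of `error_discard`, `assigned`,
#'   `unmatched`, `repeat_discard`), `clones` (0-based item indices, size 1-3
#'   when assigned) and `matched_support` (the matched, possibly reduced, pool
#'   set).
#' @export
classify_kmer <- function(counts, design, source_pool) {
  stopifnot(inherits(design, "pooling_design"))
  r <- .classify_support(as.integer(counts), design$signatures,
                         design$n_pools, design$gamma,
                         as.integer(source_pool))
  list(status = kmer_status_labels[r$status + 1L], clones = r$clones,
       matched_support = r$matched_support)
}

#' Deconvolute a single read
#'
#' Classifies every k-mer of the read against the count table and assigns the
#' read to the union B of the assigned k-mers' clone sets when 1 <= |B| <= 3;
#' otherwise the read is non-deconvolutable (reason: no assigned k-mers, or
#' clones spanning more than three).
#'
#' @param read read sequence (character string).
#' @param table a `kmer_table` built over the same pool ordering as `design`.
#' @param design a `pooling_design`.
#' @param source_pool 0-based pool of origin of the read.
#' @return list with `status` (`deconvoluted` / `non_deconvolutable`),
#'   `clones` (character clone ids), `n_clones`, `support_w` (size of the read
#'   signature, the union of the assigned clones' signatures) and `reason`.
#' @export
deconvolve_read <- function(read, table, design, source_pool) {
  stopifnot(inherits(table, "kmer_table"), inherits(design, "pooling_design"))
  if (table$n_pools != design$n_pools)
    stop("table and design disagree on the number of pools")
  r <- .kct_deconvolve(table$ptr, as.character(read),
                       as.integer(source_pool), design$signatures,
                       design$gamma)
  nb <- r$n_clones[1]
  ok <- nb >= 1 && nb <= 3
  clones <- if (ok) design$clone_ids[r$clones[1, seq_len(nb)] + 1L] else character(0)
  reason <- if (ok) NA_character_
            else if (nb == 0) "no_assigned_kmers" else "too_many_clones"
  list(status = if (ok) "deconvoluted" else "non_deconvolutable",
       clones = clones, n_clones = nb, support_w = r$support_w[1],
       reason = reason)
}

#' Deconvolute all pools
#'
#' Runs read deconvolution pool by pool. Paired-end mates are processed
#' independently as single-end reads. When `outdir` is given, every input read
#' is written once per assigned clone into `<clone_id>.fastq` files and
#' non-deconvolutable reads into `non_deconvolutable.fastq`; the assignment
#' table and per-pool summary are written as TSV alongside.
#'
#' @param pool_files pools' FASTQ files in pool-index order (character vector,
#'   or list of character vectors when a pool has several files).
#' @param table a `kmer_table` built from the same pool ordering.
#' @param design a `pooling_design`.
#' @param outdir optional output directory for per-clone FASTQ and TSVs.
#' @param gzip compress per-clone FASTQ output.
#' @param pool_indices 0-based pool index of each element of `pool_files`;
#'   defaults to `0, 1, ...`. Passing a subset (e.g. with one pool's files
#'   removed) re-runs deconvolution on the remaining pools against the same
#'   table.
#' @return an object of class `deconv_result`: list with `assignments` (one
#'   row per read: `read_id`, `pool`, `status`, `clones` (comma-separated
#'   ids), `n_clones`, `support_w`, `n_assigned_kmers`, `read_len`), `summary`
#'   (per pool: `pool`, `total`, `to_1`, `to_2`, `to_3`, `pct_deconvoluted`)
#'   and `kmer_tallies`.
#' @export
deconvolve_pools <- function(pool_files, table, design, outdir = NULL,
                             gzip = FALSE, pool_indices = NULL) {
  stopifnot(inherits(table, "kmer_table"), inherits(design, "pooling_design"))
  if (table$n_pools != design$n_pools)
    stop("table and design disagree on the number of pools: table has ",
         table$n_pools, ", design has ", design$n_pools)
  files <- if (is.list(pool_files)) pool_files else as.list(pool_files)
  if (length(files) > design$n_pools)
    stop("more pool file sets than pools in the design")
  if (is.null(pool_indices)) pool_indices <- seq_along(files) - 1L
  if (length(pool_indices) != length(files) ||
      any(pool_indices < 0 | pool_indices >= design$n_pools))
    stop("pool_indices must give a valid 0-based pool for every file set")
  write_out <- !is.null(outdir)
  if (write_out) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    started <- new.env(parent = emptyenv())  # clone id -> file already created
  }

  assign_list <- vector("list", length(files))
  summary_list <- vector("list", length(files))
  tallies <- numeric(4)
  names(tallies) <- kmer_status_labels

  for (i in seq_along(files)) {
    p <- as.integer(pool_indices[i])
    fq <- lapply(files[[i]], read_fastq)
    ids <- unlist(lapply(fq, `[[`, "id"), use.names = FALSE)
    seqs <- unlist(lapply(fq, `[[`, "seq"), use.names = FALSE)
    quals <- unlist(lapply(fq, `[[`, "qual"), use.names = FALSE)
    r <- .kct_deconvolve(table$ptr, seqs, p, design$signatures, design$gamma)
    tallies <- tallies + r$kmer_tallies
    nb <- r$n_clones
    ok <- nb >= 1 & nb <= 3
    clone_str <- rep(NA_character_, length(seqs))
    if (any(ok)) {
      cm <- matrix(design$clone_ids[r$clones[ok, , drop = FALSE] + 1L],
                   ncol = 3)
      clone_str[ok] <- apply(cm, 1, function(z) paste(z[!is.na(z)], collapse = ","))
    }
    assign_list[[i]] <- data.frame(
      read_id = ids, pool = p,
      status = ifelse(ok, "deconvoluted", "non_deconvolutable"),
      clones = clone_str, n_clones = nb, support_w = r$support_w,
      n_assigned_kmers = r$n_assigned, read_len = nchar(seqs))
    summary_list[[i]] <- data.frame(
      pool = p, total = length(seqs),
      to_1 = sum(nb == 1), to_2 = sum(nb == 2), to_3 = sum(nb == 3),
      pct_deconvoluted = 100 * sum(ok) / max(1, length(seqs)))

    if (write_out) {
      for (item in sort(unique(unlist(
          apply(r$clones[ok, , drop = FALSE], 2, unique))))) {
        if (is.na(item)) next
        sel <- ok & (r$clones[, 1] %in% item | r$clones[, 2] %in% item |
                     r$clones[, 3] %in% item)
        cid <- design$clone_ids[item + 1L]
        f <- file.path(outdir, paste0(cid, ext))
        append_fastq(f, ids[sel], seqs[sel], quals[sel], gzip,
                     exists(cid, envir = started))
        assign(cid, TRUE, envir = started)
      }
      if (any(!ok)) {
        f <- file.path(outdir, paste0("non_deconvolutable", ext))
        append_fastq(f, ids[!ok], seqs[!ok], quals[!ok], gzip,
                     exists(".nd", envir = started))
        assign(".nd", TRUE, envir = started)
      }
    }
  }
  res <- structure(list(assignments = do.call(rbind, assign_list),
                        summary = do.call(rbind, summary_list),
                        kmer_tallies = tallies),
                   class = "deconv_result")
  if (write_out) {
    write.table(res$assignments, file.path(outdir, "assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$summary, file.path(outdir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$outdir <- outdir
  }
  res
}

append_fastq <- function(path, ids, seqs, quals, gzip, append) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq", append = append,
                              qualities = Biostrings::BStringSet(quals),
                              compress = gzip)
}

#' @export
print.deconv_result <- function(x, ...) {
  tot <- sum(x$summary$total)
  dec <- sum(x$summary$to_1 + x$summary$to_2 + x$summary$to_3)
  cat(sprintf("Deconvolution of %d reads in %d pools: %.2f%% deconvoluted\n",
              tot, nrow(x$summary), 100 * dec / max(1, tot)))
  cat(sprintf("  to 1 clone: %d   to 2: %d   to 3: %d\n",
              sum(x$summary$to_1), sum(x$summary$to_2), sum(x$summary$to_3)))
  invisible(x)
}

#' Histogram of read signature sizes
#'
#' Tallies the size of each read's signature (the union of the signatures of
#' the clones it was assigned to; 0 for reads with no assigned k-mers). For a
#' design with L layers, single-clone reads sit at w = L and overlap reads in
#' `[2L-2*gamma, 2L]` / `[3L-3*gamma, 3L]`.
#'
#' @param x a `deconv_result` or its `assignments` data.frame.
#' @return data.frame with columns `w` and `reads`.
#' @export
read_signature_histogram <- function(x) {
  a <- if (inherits(x, "deconv_result")) x$assignments else x
  t <- table(a$support_w)
  data.frame(w = as.integer(names(t)), reads = as.integer(t))
}

#' Overall deconvolution rate
#'
#' @param x a `deconv_result` or its `assignments` data.frame.
#' @return fraction of input reads deconvoluted to 1-3 clones.
#' @export
deconvolution_rate <- function(x) {
  a <- if (inherits(x, "deconv_result")) x$assignments else x
  mean(a$status == "deconvoluted")
}

#' @export
plot.deconv_result <- function(x, ...) {
  h <- read_signature_histogram(x)
  graphics::barplot(setNames(h$reads, h$w), xlab = "read signature size w",
                    ylab = "reads", ...)
  invisible(x)
}
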
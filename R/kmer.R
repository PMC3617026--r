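# Per-pool canonical k-mer count table.

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer and
#' its reverse complement, so a sequence and its reverse complement always
#' count the same table entry.
#'
#' @param kmers character vector of ACGT strings (length 1..31 each).
#' @return character vector of the same length.
#' @examples
#' kmer_canonical(c("ACG", "TTT"))  # "ACG", "AAA"
#' @export
kmer_canonical <- function(kmers) {
  .canonical_kmers(as.character(kmers))
}

#' Build the per-pool k-mer count table
#'
#' Counts, for every distinct canonical k-mer, its occurrences in the reads of
#' each pool: every window of `k` consecutive ACGT bases contributes one count
#' to its pool's slot (windows containing non-ACGT symbols are skipped).
#' Counts saturate at `cap`; downstream classification only uses positivity
#' and relative magnitude.
#'
#' @param pools the pools' reads in pool-index order: a character vector of
#'   FASTQ paths (one file per pool), a list of character vectors of FASTQ
#'   paths (several files per pool, e.g. the two mate files), or a list of
#'   character vectors of raw sequences.
#' @param k k-mer length (default 26; 1..31).
#' @param n_pools number of pools; defaults to `length(pools)`.
#' @param cap saturation value for counts.
#' @return an object of class `kmer_table` (an external pointer wrapper with
#'   fields `k`, `n_pools`). The table lives for the R session; use
#'   [kmer_table_df()] / [write_kmer_table()] for a portable export.
#' @examples
#' tab <- kmer_count_table(list("ACGT"), k = 3)
#' kmer_table_df(tab)
#' @export
kmer_count_table <- function(pools, k = 26, n_pools = length(pools),
                             cap = 65535L) {
  stopifnot(k >= 1, k <= 31, n_pools == length(pools))
  ptr <- .kct_new(as.integer(k), as.integer(n_pools), as.integer(cap))
  windows <- numeric(n_pools)
  for (p in seq_len(n_pools)) {
    seqs <- pool_sequences(if (is.list(pools)) pools[[p]] else pools[[p]],
                           pool = p - 1)
    windows[p] <- .kct_add_reads(ptr, seqs, p - 1L)
  }
  structure(list(ptr = ptr, k = as.integer(k), n_pools = as.integer(n_pools),
                 windows = windows),
            class = "kmer_table")
}

# Resolve a pool's entry to raw sequences: file paths are read as FASTQ,
# anything else is taken as sequence.
pool_sequences <- function(x, pool) {
  x <- as.character(x)
  if (length(x) > 0 && all(grepl("\\.(fastq|fq)(\\.gz)?$", x))) {
    missing <- !file.exists(x)
    if (any(missing))
      stop("pool ", pool, ": missing or unreadable file ", x[missing][1])
    unlist(lapply(x, function(f) {
      as.character(Biostrings::readDNAStringSet(f, format = "fastq"))
    }), use.names = FALSE)
  } else {
    x
  }
}

#' @export
print.kmer_table <- function(x, ...) {
  info <- .kct_info(x$ptr)
  cat(sprintf("k-mer count table: k = %d, %d pools, %s distinct k-mers\n",
              info$k, info$n_pools, format(info$n_kmers, big.mark = ",")))
  invisible(x)
}

#' Query k-mer counts
#'
#' @param table a `kmer_table`.
#' @param kmers character vector of k-mers (canonicalised before lookup).
#' @return integer matrix, one row per query, one column per pool.
#' @export
kmer_counts <- function(table, kmers) {
  stopifnot(inherits(table, "kmer_table"))
  m <- .kct_lookup(table$ptr, as.character(kmers))
  rownames(m) <- kmers
  colnames(m) <- 0:(table$n_pools - 1)
  m
}

#' Export the full table
#'
#' Intended for small tables (fixtures, inspection): the count matrix of every
#' stored canonical k-mer, lexicographically sorted. `write_kmer_table()`
#' writes it as TSV with a `kmer` column and one `pool_<i>` column per pool.
#'
#' @param table a `kmer_table`.
#' @param path TSV output path.
#' @return data.frame with `kmer` and per-pool count columns.
#' @export
kmer_table_df <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  d <- .kct_dump(table$ptr)
  df <- data.frame(kmer = d$kmer, d$counts)
  colnames(df) <- c("kmer", paste0("pool_", 0:(table$n_pools - 1)))
  df
}

#' @rdname kmer_table_df
#' @export
write_kmer_table <- function(table, path) {
  write.table(kmer_table_df(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Histogram of k-mer signature sizes
#'
#' Tallies, over all distinct stored k-mers, the size w of the support (number
#' of pools with a positive count). For clone-unique error-free sequence the
#' mass concentrates at w = L; k-mers from clone overlaps peak in the 2- and
#' 3-clone union ranges.
#'
#' @param table a `kmer_table`.
#' @return data.frame with columns `w` and `kmers` (only occupied sizes).
#' @export
kmer_support_histogram <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  h <- .kct_support_hist(table$ptr)
  df <- data.frame(w = seq_along(h) - 1L, kmers = h)
  df[df$kmers > 0, , drop = FALSE]
}

#' Guaranteed exact-match length under bounded mismatches
#'
#' The largest m such that *every* placement of at most `max_mismatches`
#' mismatching positions within an overlap of `overlap_length` bases leaves an
#' exact run of at least m bases: by pigeonhole,
#' `ceiling((overlap_length - max_mismatches) / (max_mismatches + 1))`.
#' This is the worst-case perfect-match length that motivates the choice of k:
#' with a 78-base overlap and at most two mismatches a 26-base exact match
#' must occur.
#'
#' @param overlap_length overlap size in bases (> `max_mismatches`).
#' @param max_mismatches maximum number of mismatches (>= 0).
#' @return integer.
#' @examples
#' guaranteed_match_length(78, 2)  # 26
#' @export
guaranteed_match_length <- function(overlap_length, max_mismatches) {
  if (!(overlap_length > max_mismatches && max_mismatches >= 0))
    stop("require overlap_length > max_mismatches >= 0")
  as.integer(ceiling((overlap_length - max_mismatches) / (max_mismatches + 1)))
}

#' @export
plot.kmer_table <- function(x, ...) {
  h <- kmer_support_histogram(x)
  graphics::barplot(setNames(h$kmers, h$w), xlab = "k-mer signature size w",
                    ylab = "distinct k-mers", ...)
  invisible(x)
}
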
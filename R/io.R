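# FASTQ I/O (via Biostrings; gzip transparent) and quality trimming.

#' Read and write FASTQ
#'
#' Thin wrappers around Biostrings with plain character vectors in and out;
#' gzipped files are handled transparently (`.gz` suffix on write).
#'
#' @param path file path.
#' @param ids,seqs,quals character vectors; `quals` defaults to constant Q40.
#' @param gzip compress output.
#' @return `read_fastq()`: list with `id`, `seq`, `qual` character vectors.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(id = names(x), seq = unname(as.character(x)),
       qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(path, ids, seqs, quals = NULL, gzip = FALSE) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = gzip)
  invisible(path)
}

#' Quality trimming and read filtering
#'
#' `quality_trim()` applies the preprocessing used ahead of deconvolution to
#' in-memory records: a sliding window of `window` bases scans left to right
#' and the read is truncated at the start of the first window whose mean Phred
#' quality falls below `min_quality`; trimmed reads shorter than `min_length`
#' bases, or containing any `N` (when `drop_n`), are discarded.
#' `trim_fastq()` is the file-to-file version.
#'
#' @param ids,seqs,quals parallel character vectors (Phred+33 qualities).
#' @param window sliding window length in bases.
#' @param min_quality minimum mean Phred quality of a window.
#' @param min_length minimum surviving read length in bases.
#' @param drop_n drop reads containing `N` after trimming.
#' @return `quality_trim()`: list with the surviving `id`, `seq`, `qual` and a
#'   `counts` vector (`input`, `kept`, `trimmed`, `dropped_short`,
#'   `dropped_n`); `kept + dropped_* = input`, and `trimmed` counts kept reads
#'   that were shortened. `trim_fastq()` returns the counts invisibly.
#' @examples
#' quality_trim("r1", "ACGTN", "IIII#", min_length = 2)$counts
#' @export
quality_trim <- function(ids, seqs, quals, window = 4, min_quality = 23,
                         min_length = 36, drop_n = TRUE) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals),
            min_quality >= 0, min_length >= 0)
  if (any(nchar(seqs) != nchar(quals)))
    stop("malformed record: sequence and quality lengths differ (record ",
         which(nchar(seqs) != nchar(quals))[1], ")")
  keep_len <- .trim_lengths(quals, as.integer(window), min_quality)
  trimmed <- keep_len < nchar(seqs)
  seqs <- substr(seqs, 1, keep_len)
  quals <- substr(quals, 1, keep_len)
  long_enough <- keep_len >= min_length
  has_n <- grepl("N", seqs, fixed = TRUE)
  keep <- long_enough & (!drop_n | !has_n)
  counts <- c(input = length(seqs), kept = sum(keep),
              trimmed = sum(trimmed & keep),
              dropped_short = sum(!long_enough),
              dropped_n = sum(long_enough & drop_n & has_n))
  list(id = ids[keep], seq = seqs[keep], qual = quals[keep], counts = counts)
}

#' @rdname quality_trim
#' @param input,output FASTQ paths (gzip by suffix).
#' @export
trim_fastq <- function(input, output, window = 4, min_quality = 23,
                       min_length = 36, drop_n = TRUE) {
  x <- read_fastq(input)
  out <- quality_trim(x$id, x$seq, x$qual, window = window,
                      min_quality = min_quality, min_length = min_length,
                      drop_n = drop_n)
  write_fastq(output, out$id, out$seq, out$qual,
              gzip = grepl("\\.gz$", output))
  invisible(out$counts)
}
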
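# In-silico pooled sequencing: synthetic genome, tiled clone layout, per-pool
# paired-end reads with a provenance trail.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a genome sequence
#'
#' Generates an i.i.d. background of the requested GC content and optionally
#' plants repeat families: each family is one random unit copied `copies`
#' times to non-overlapping random positions, with every copy independently
#' diverged by per-base substitutions at rate `divergence`.
#'
#' @param length genome length in bases.
#' @param gc GC fraction in `[0, 1]`.
#' @param repeats optional data.frame (or list coercible to one) with columns
#'   `unit_length`, `copies`, `divergence`.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return a single character string of A/C/G/T, with attributes
#'   `repeat_units` (the family unit sequences) and `repeat_copies`
#'   (data.frame `family`, `start`, `end`, 0-based half-open) recording the
#'   planted repeats.
#' @examples
#' g <- sim_genome(1e4, gc = 0.44, seed = 1)
#' nchar(g)
#' @export
sim_genome <- function(length, gc = 0.44, repeats = NULL, seed = NULL) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  with_seed(seed, {
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    bases <- c("A", "C", "G", "T")
    g <- sample(bases, length, replace = TRUE, prob = prob)
    units <- character(0)
    copies_df <- data.frame(family = integer(0), start = integer(0),
                            end = integer(0))
    if (!is.null(repeats)) {
      repeats <- as.data.frame(repeats)
      placed_start <- integer(0); placed_end <- integer(0)
      for (f in seq_len(nrow(repeats))) {
        ul <- repeats$unit_length[f]
        copies <- repeats$copies[f]
        div <- repeats$divergence[f]
        if (ul > length) stop("infeasible repeat placement: unit longer than genome")
        unit <- sample(bases, ul, replace = TRUE, prob = prob)
        for (cp in seq_len(copies)) {
          ok <- FALSE
          for (try in 1:1000) {
            s <- sample.int(length - ul + 1, 1) - 1L  # 0-based
            if (!any(s < placed_end & s + ul > placed_start)) { ok <- TRUE; break }
          }
          if (!ok) stop("infeasible repeat placement: no room for copy ", cp,
                        " of family ", f)
          copy <- unit
          nmut <- rbinom(1, ul, div)
          if (nmut > 0) {
            at <- sample.int(ul, nmut)
            shift <- sample.int(3, nmut, replace = TRUE)
            copy[at] <- bases[(match(copy[at], bases) - 1 + shift) %% 4 + 1]
          }
          g[(s + 1):(s + ul)] <- copy
          placed_start <- c(placed_start, s); placed_end <- c(placed_end, s + ul)
          copies_df <- rbind(copies_df,
                             data.frame(family = f, start = s, end = s + ul))
        }
        units <- c(units, paste(unit, collapse = ""))
      }
    }
    structure(paste(g, collapse = ""), repeat_units = units,
              repeat_copies = copies_df)
  })
}

#' Lay out tiled clones on a genome
#'
#' Places `n_clones` left to right with lengths ~ Normal(`mean_length`,
#' `sd_length`) (truncated positive) and consecutive overlaps ~
#' Normal(`mean_overlap`, `sd_overlap`) (truncated nonnegative), mimicking a
#' minimum tiling path. Coordinates are 0-based half-open. No base may be
#' covered by more than 3 clones.
#'
#' @param genome_length total genome length.
#' @param n_clones number of clones.
#' @param mean_length,sd_length clone length distribution (bases).
#' @param mean_overlap,sd_overlap overlap of consecutive clones (bases).
#' @param clone_ids optional labels, default `"clone_0" ...`.
#' @param seed optional integer seed.
#' @return data.frame of class `clone_layout` with columns `clone_id`,
#'   `start`, `end`.
#' @examples
#' sim_clone_layout(1e6, 9, 120000, 0, 10000, 0, seed = 1)
#' @export
sim_clone_layout <- function(genome_length, n_clones, mean_length,
                             sd_length = 0, mean_overlap = 0, sd_overlap = 0,
                             clone_ids = NULL, seed = NULL) {
  stopifnot(n_clones >= 1, mean_length > 0, mean_overlap >= 0)
  if (is.null(clone_ids)) clone_ids <- paste0("clone_", 0:(n_clones - 1))
  with_seed(seed, {
    lens <- round(rnorm(n_clones, mean_length, sd_length))
    lens[lens < 1] <- 1
    ovls <- round(rnorm(n_clones - 1, mean_overlap, sd_overlap))
    ovls[ovls < 0] <- 0
    starts <- integer(n_clones)
    for (i in seq_len(n_clones)[-1]) {
      ov <- min(ovls[i - 1], lens[i - 1] - 1)
      starts[i] <- starts[i - 1] + lens[i - 1] - ov
    }
    ends <- starts + lens
    if (ends[n_clones] > genome_length)
      stop("infeasible tiling: clones extend past the genome end (need ",
           ends[n_clones], " bases)")
    layout <- data.frame(clone_id = clone_ids, start = starts, end = ends)
    class(layout) <- c("clone_layout", "data.frame")
    validate_clone_layout(layout, genome_length)
    layout
  })
}

validate_clone_layout <- function(layout, genome_length = NULL) {
  stopifnot(all(layout$start >= 0), all(layout$start < layout$end))
  if (!is.null(genome_length)) stopifnot(all(layout$end <= genome_length))
  o <- order(layout$start, layout$end)
  s <- layout$start[o]; e <- layout$end[o]
  if (length(s) > 3 && any(s[-(1:3)] < e[seq_len(length(e) - 3)]))
    stop("layout invalid: a base is covered by more than 3 clones")
  invisible(layout)
}

# Overlap relation between clones (shared bases > 0), as a list of 0-based
# item index vectors, excluding the clone itself.
clone_overlaps <- function(layout) {
  n <- nrow(layout)
  lapply(seq_len(n), function(i) {
    hit <- which(layout$start < layout$end[i] & layout$start[i] < layout$end)
    setdiff(hit, i) - 1L
  })
}

#' Simulate pooled paired-end sequencing
#'
#' Draws paired-end reads pool by pool: each pool's reads come only from the
#' clones assigned to that pool by the design, in proportion to clone length.
#' Insert lengths are Normal(`insert_mean`, `insert_sd`) clamped to
#' `[read_length, clone length]`; fragments never extend past clone ends
#' (clone-end sequence is clone sequence only, as in BAC sequencing).
#' Substitution errors are i.i.d. per base at `error_rate` (no indels).
#' Optionally a fraction of pairs is drawn from a contaminant sequence and
#' flagged. Read names carry the full provenance,
#' `<id>|<clone>|<pool>|<fragment start>|<fragment end>|<contam>` with `|` as
#' reserved separator, and a truth TSV maps every mate to its source.
#'
#' @param design a `pooling_design`; `design$n` must equal `nrow(layout)`.
#' @param layout a `clone_layout` (row i is design item i-1).
#' @param genome genome sequence (single character string).
#' @param outdir output directory, created if needed.
#' @param read_length,insert_mean,insert_sd,error_rate read simulation
#'   parameters; defaults follow a typical short-read pooled-BAC experiment
#'   (104-base mates, 327-base inserts, 1% error).
#' @param depth_per_pool target per-pool sequencing depth (x coverage of the
#'   pool's total clone bases); alternatively give `pairs_per_pool` directly.
#' @param pairs_per_pool number of read pairs per pool (overrides depth).
#' @param contaminant optional contaminant sequence (character string).
#' @param contaminant_fraction fraction of pairs drawn from the contaminant.
#' @param seed optional integer seed (byte-identical outputs for fixed seed).
#' @param gzip write gzipped FASTQ.
#' @return an object of class `pool_sim`: list with `files` (data.frame:
#'   `pool`, `r1`, `r2`), `truth` (path of the truth TSV), and `params`.
#' @export
sim_pool_reads <- function(design, layout, genome, outdir,
                           read_length = 104, insert_mean = 327,
                           insert_sd = round(0.1 * insert_mean),
                           error_rate = 0.01,
                           depth_per_pool = NULL, pairs_per_pool = NULL,
                           contaminant = NULL, contaminant_fraction = 0,
                           seed = NULL, gzip = FALSE) {
  stopifnot(inherits(design, "pooling_design"))
  if (design$n != nrow(layout)) stop("design and layout disagree on clone count")
  if (read_length > insert_mean) stop("read_length must not exceed insert_mean")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (is.null(depth_per_pool) && is.null(pairs_per_pool))
    stop("give depth_per_pool or pairs_per_pool")
  if (contaminant_fraction > 0 && is.null(contaminant))
    stop("contaminant_fraction > 0 requires a contaminant sequence")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  members <- pool_members(design)
  clone_seqs <- substring(genome, layout$start + 1, layout$end)
  clone_lens <- nchar(clone_seqs)
  ext <- if (gzip) ".fastq.gz" else ".fastq"

  with_seed(seed, {
    files <- data.frame(pool = 0:(design$n_pools - 1),
                        r1 = character(design$n_pools),
                        r2 = character(design$n_pools))
    truth_path <- file.path(outdir, "truth.tsv")
    tcon <- file(truth_path, "w")
    on.exit(close(tcon))
    writeLines("read_id\tclone_id\tpool\tstart\tend\tis_contaminant", tcon)

    for (p in 0:(design$n_pools - 1)) {
      items <- members[[p + 1]]          # 0-based item indices
      lens <- clone_lens[items + 1]
      eligible <- lens >= insert_mean
      if (any(!eligible)) {
        warning("pool ", p, ": skipping ", sum(!eligible),
                " clone(s) shorter than the mean insert")
        items <- items[eligible]; lens <- lens[eligible]
      }
      f1 <- file.path(outdir, sprintf("pool_%03d_R1%s", p, ext))
      f2 <- file.path(outdir, sprintf("pool_%03d_R2%s", p, ext))
      files$r1[p + 1] <- f1; files$r2[p + 1] <- f2
      if (length(items) == 0) {
        warning("pool ", p, " has no usable clones; writing empty files")
        write_fastq(f1, character(0), character(0), gzip = gzip)
        write_fastq(f2, character(0), character(0), gzip = gzip)
        next
      }
      n_pairs <- if (!is.null(pairs_per_pool)) pairs_per_pool else {
        round(depth_per_pool * sum(lens) / (2 * read_length))
      }
      n_contam <- round(contaminant_fraction * n_pairs)
      n_bac <- n_pairs - n_contam

      src_item <- sample(seq_along(items), n_bac, replace = TRUE, prob = lens)
      src_id <- layout$clone_id[items[src_item] + 1]
      src_len <- lens[src_item]
      src_seq <- clone_seqs[items[src_item] + 1]
      contam_flag <- rep(0L, n_bac)
      if (n_contam > 0) {
        clen <- nchar(contaminant)
        if (clen < insert_mean) stop("contaminant shorter than the mean insert")
        src_id <- c(src_id, rep("contaminant", n_contam))
        src_len <- c(src_len, rep(clen, n_contam))
        src_seq <- c(src_seq, rep(contaminant, n_contam))
        contam_flag <- c(contam_flag, rep(1L, n_contam))
      }
      ins <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)),
                       read_length), src_len)
      fstart <- floor(runif(n_pairs) * (src_len - ins + 1))  # 0-based
      r1 <- substr(src_seq, fstart + 1, fstart + read_length)
      r2 <- revcomp(substr(src_seq, fstart + ins - read_length + 1, fstart + ins))
      r1 <- add_read_errors(r1, error_rate)
      r2 <- add_read_errors(r2, error_rate)

      base <- sprintf("p%03d_%07d|%s|%d|%d|%d|%d", p, seq_len(n_pairs),
                      src_id, p, fstart, fstart + ins, contam_flag)
      write_fastq(f1, paste0(base, "/1"), r1, gzip = gzip)
      write_fastq(f2, paste0(base, "/2"), r2, gzip = gzip)
      writeLines(c(sprintf("%s/1\t%s\t%d\t%d\t%d\t%d", base, src_id, p,
                           fstart, fstart + read_length, contam_flag),
                   sprintf("%s/2\t%s\t%d\t%d\t%d\t%d", base, src_id, p,
                           fstart + ins - read_length, fstart + ins, contam_flag)),
                 tcon)
    }
    structure(list(files = files, truth = truth_path,
                   params = list(read_length = read_length,
                                 insert_mean = insert_mean,
                                 insert_sd = insert_sd,
                                 error_rate = error_rate,
                                 contaminant_fraction = contaminant_fraction)),
              class = "pool_sim")
  })
}

# i.i.d. per-base substitutions; replacement base always differs from the
# original.
add_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  bases <- c("A", "C", "G", "T")
  rl <- nchar(reads[1])
  hit <- which(runif(length(reads) * rl) < rate)
  for (j in hit) {
    r <- (j - 1) %/% rl + 1
    pos <- (j - 1) %% rl + 1
    cur <- substr(reads[r], pos, pos)
    new <- bases[(match(cur, bases) - 1 + sample.int(3, 1)) %% 4 + 1]
    substr(reads[r], pos, pos) <- new
  }
  reads
}

#' @export
print.pool_sim <- function(x, ...) {
  cat(sprintf("Pooled read simulation: %d pools, truth table %s\n",
              nrow(x$files), x$truth))
  invisible(x)
}

#' Read a simulation truth table
#'
#' @param path path of the `truth.tsv` written by [sim_pool_reads()].
#' @return data.frame with columns `read_id`, `clone_id`, `pool`, `start`,
#'   `end`, `is_contaminant`.
#' @export
read_truth <- function(path) {
  read.delim(path, colClasses = c("character", "character", "integer",
                                  "integer", "integer", "integer"))
}
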
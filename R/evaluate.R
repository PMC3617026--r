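# Scoring deconvolution output against simulation truth.

split_clones <- function(x) strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE)

#' Overlap-aware correctness of deconvolution
#'
#' Fraction of *deconvoluted* reads whose assigned clone set contains the
#' source clone or any clone overlapping the source clone in the layout
#' (sequence in an overlap legitimately belongs to both clones).
#'
#' @param assignments a `deconv_result` or its `assignments` data.frame.
#' @param truth truth data.frame from [read_truth()] (or the file path).
#' @param layout the `clone_layout` used in the simulation.
#' @return fraction in `[0, 1]`.
#' @export
correctness_rate <- function(assignments, truth, layout) {
  a <- if (inherits(assignments, "deconv_result")) assignments$assignments else assignments
  if (is.character(truth)) truth <- read_truth(truth)
  a <- a[a$status == "deconvoluted", , drop = FALSE]
  if (nrow(a) == 0) return(NaN)
  m <- match(a$read_id, truth$read_id)
  if (anyNA(m)) stop("read missing from truth table: ", a$read_id[which(is.na(m))[1]])
  src <- truth$clone_id[m]
  ov <- clone_overlaps(layout)
  accept <- lapply(seq_len(nrow(layout)), function(i) {
    c(layout$clone_id[i], layout$clone_id[ov[[i]] + 1L])
  })
  names(accept) <- layout$clone_id
  assigned <- split_clones(a$clones)
  hit <- mapply(function(cl, s) {
    !is.na(match(s, names(accept))) && any(cl %in% accept[[s]])
  }, assigned, src)
  mean(hit)
}

#' Mate concordance of paired-end deconvolution
#'
#' Mates are deconvoluted independently; this checks how often they agree.
#' Pairs with both mates non-deconvolutable are excluded. Among the remaining
#' (eligible) pairs, a pair is concordant iff both mates were deconvoluted and
#' one mate's clone set contains the other's.
#'
#' @param assignments a `deconv_result` or its `assignments` data.frame; mates
#'   are identified by the trailing `/1` / `/2` of `read_id`.
#' @return fraction concordant / eligible.
#' @export
mate_concordance <- function(assignments) {
  a <- if (inherits(assignments, "deconv_result")) assignments$assignments else assignments
  base <- sub("/[12]$", "", a$read_id)
  mate <- sub("^.*/", "", a$read_id)
  if (!all(mate %in% c("1", "2"))) stop("unpaired input: read ids must end in /1 or /2")
  o1 <- which(mate == "1"); o2 <- which(mate == "2")
  m <- match(base[o1], base[o2])
  if (anyNA(m) || length(o1) != length(o2))
    stop("unpaired input: every read needs both mates")
  o2 <- o2[m]
  d1 <- a$status[o1] == "deconvoluted"
  d2 <- a$status[o2] == "deconvoluted"
  eligible <- d1 | d2
  if (!any(eligible)) return(NaN)
  c1 <- split_clones(a$clones[o1])
  c2 <- split_clones(a$clones[o2])
  conc <- d1 & d2 & mapply(function(x, y) {
    length(intersect(x, y)) == min(length(x), length(y))
  }, c1, c2)
  sum(conc[eligible]) / sum(eligible)
}

#' Clone size from fingerprint band counts
#'
#' Restriction-fingerprint band counts are proportional to clone length;
#' `calibrate_band_multiplier()` estimates the bases-per-band multiplier from
#' a fingerprinted library of assumed mean length, and `estimate_clone_size()`
#' applies it.
#'
#' @param band_count number of fingerprint bands of a clone (> 0).
#' @param multiplier bases per band (e.g. 1175 for a library whose mean clone
#'   length of 106 kb corresponds to a mean band count of about 90).
#' @param band_counts vector of band counts of the fingerprinted library.
#' @param assumed_mean_length assumed mean clone length of that library.
#' @return estimated size in bases / the multiplier in bases per band.
#' @examples
#' estimate_clone_size(100, 1175)
#' calibrate_band_multiplier(c(80, 100), 106000)
#' @export
estimate_clone_size <- function(band_count, multiplier) {
  if (any(band_count <= 0)) stop("band_count must be positive")
  band_count * multiplier
}

#' @rdname estimate_clone_size
#' @export
calibrate_band_multiplier <- function(band_counts, assumed_mean_length) {
  if (length(band_counts) == 0) stop("empty band count list")
  if (assumed_mean_length <= 0) stop("assumed_mean_length must be positive")
  assumed_mean_length / mean(band_counts)
}

#' Per-clone depth table
#'
#' Sums the sequenced bases assigned to each clone and derives the expected
#' coverage (assigned bases / clone size) that a coverage-aware assembler
#' needs. A read assigned to several clones contributes its bases to each of
#' them, mirroring the depth amplification of multi-clone assignment.
#'
#' @param assignments a `deconv_result` or its `assignments` data.frame.
#' @param sizes named numeric vector of clone sizes in bases (names = clone
#'   ids); required for every assigned clone.
#' @return data.frame with columns `clone_id`, `reads`, `bases`, `size`,
#'   `coverage`.
#' @export
per_clone_depth <- function(assignments, sizes) {
  a <- if (inherits(assignments, "deconv_result")) assignments$assignments else assignments
  a <- a[a$status == "deconvoluted", , drop = FALSE]
  cl <- split_clones(a$clones)
  reps <- lengths(cl)
  df <- data.frame(clone_id = unlist(cl), len = rep(a$read_len, reps))
  reads <- tapply(df$len, df$clone_id, length)
  bases <- tapply(df$len, df$clone_id, sum)
  ids <- names(reads)
  if (any(!ids %in% names(sizes)))
    stop("missing size for clone ", ids[!ids %in% names(sizes)][1])
  out <- data.frame(clone_id = ids, reads = as.integer(reads),
                    bases = as.numeric(bases), size = as.numeric(sizes[ids]))
  out$coverage <- out$bases / out$size
  rownames(out) <- NULL
  out
}

#' Evaluation report for a deconvolution run
#'
#' Bundles the quality metrics of a run against simulation truth: overall
#' deconvolution rate, overlap-aware correctness, mate concordance and (when
#' clone sizes are given) the per-clone depth table.
#'
#' @param result a `deconv_result`.
#' @param truth truth data.frame or path.
#' @param layout the simulation's `clone_layout`.
#' @param sizes optional named clone sizes for the depth table; defaults to
#'   the layout lengths.
#' @return an object of class `deconv_eval`.
#' @export
evaluate_deconvolution <- function(result, truth, layout, sizes = NULL) {
  if (is.character(truth)) truth <- read_truth(truth)
  if (is.null(sizes)) {
    sizes <- setNames(layout$end - layout$start, layout$clone_id)
  }
  out <- list(deconvolution_rate = deconvolution_rate(result),
              correctness_rate = correctness_rate(result, truth, layout),
              mate_concordance = mate_concordance(result),
              depth = per_clone_depth(result, sizes))
  class(out) <- "deconv_eval"
  out
}

#' @export
print.deconv_eval <- function(x, ...) {
  cat("Deconvolution evaluation\n")
  cat(sprintf("  deconvolution rate: %.2f%%\n", 100 * x$deconvolution_rate))
  cat(sprintf("  correctness (overlap-aware): %.2f%%\n", 100 * x$correctness_rate))
  cat(sprintf("  mate concordance: %.2f%%\n", 100 * x$mate_concordance))
  cat(sprintf("  mean clone coverage: %.1fx over %d clones\n",
              mean(x$depth$coverage), nrow(x$depth)))
  invisible(x)
}
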
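# Decoding binary pool-level marker calls (e.g. GoldenGate OPA genotyping of
# the pools) to clone assignments by error minimisation.

#' Decode one marker's positive-pool set
#'
#' For a marker observed positive in pool set S, finds the clone subset T
#' (1 <= |T| <= `max_set_size`) minimising the error count
#' \eqn{E(T) = |P(T) \setminus S| + |S \setminus P(T)|}, where P(T) is the
#' union of the pools of the clones in T ("extra" plus "missing"
#' observations). The marker is non-decodable when the minimum exceeds
#' `error_cap`. The search is restricted to candidate clones sharing at least
#' `L - error_cap` pools with S; any clone below that bound already
#' contributes more than `error_cap` missing observations, so the restriction
#' never changes a decodable argmin (for non-decodable markers the reported
#' `error_count` is the minimum within the candidate space, itself >
#' `error_cap`). Ties are broken by smaller |T|, then by clone order.
#'
#' @param positive_pools integer vector of 0-based pool indices.
#' @param design a `pooling_design`.
#' @param max_set_size largest clone set considered (default 3).
#' @param error_cap maximum tolerated error count (default 3).
#' @return list with `clones` (0-based item indices; empty when
#'   non-decodable), `error_count` (NA for an empty call set) and `decodable`.
#' @examples
#' d <- std_design(3, 3, 1, 9)
#' decode_marker(signatures(d)[1, ], d)  # clone 0, E = 0
#' @export
decode_marker <- function(positive_pools, design, max_set_size = 3,
                          error_cap = 3) {
  stopifnot(inherits(design, "pooling_design"))
  S <- unique(as.integer(positive_pools))
  if (length(S) == 0) {
    return(list(clones = integer(0), error_count = NA_integer_,
                decodable = FALSE))
  }
  if (any(S < 0 | S >= design$n_pools)) stop("pool index out of [0, L*P)")
  inS <- matrix(design$signatures %in% S, nrow = design$n)
  cand <- which(rowSums(inS) >= design$layers - error_cap)
  if (length(cand) == 0) {
    return(list(clones = integer(0), error_count = NA_integer_,
                decodable = FALSE))
  }
  r <- .decode_search(S, design$signatures[cand, , drop = FALSE],
                      design$n_pools, as.integer(max_set_size))
  clones <- sort(cand[r$members + 1L] - 1L)
  if (r$error > error_cap) {
    list(clones = integer(0), error_count = r$error, decodable = FALSE)
  } else {
    list(clones = clones, error_count = r$error, decodable = TRUE)
  }
}

#' Decode a marker-by-pool call matrix
#'
#' @param calls binary matrix, rows = markers (rownames used as marker ids),
#'   columns = the design's `n_pools` pools in 0-based order.
#' @param design a `pooling_design`.
#' @param layout optional `clone_layout`; when given, multi-clone assignments
#'   are cross-checked for mutual overlap (clones carrying the same marker
#'   should be neighbours) in an `overlap_consistent` column.
#' @inheritParams decode_marker
#' @return list with `assignments` (data.frame: `marker`, `clones`
#'   (comma-separated clone ids), `n_clones`, `error_count`, `decodable`, and
#'   optionally `overlap_consistent`) and `error_histogram` (data.frame of
#'   `error_count`, `markers`).
#' @export
decode_markers <- function(calls, design, max_set_size = 3, error_cap = 3,
                           layout = NULL) {
  stopifnot(inherits(design, "pooling_design"))
  calls <- as.matrix(calls)
  if (ncol(calls) != design$n_pools)
    stop("call matrix has ", ncol(calls), " columns but the design has ",
         design$n_pools, " pools")
  if (!all(calls %in% c(0, 1))) stop("calls must be binary")
  ids <- rownames(calls)
  if (is.null(ids)) ids <- paste0("marker_", seq_len(nrow(calls)) - 1)
  res <- lapply(seq_len(nrow(calls)), function(i) {
    decode_marker(which(calls[i, ] > 0) - 1L, design, max_set_size, error_cap)
  })
  df <- data.frame(
    marker = ids,
    clones = vapply(res, function(r) {
      if (length(r$clones)) paste(design$clone_ids[r$clones + 1L], collapse = ",")
      else NA_character_
    }, character(1)),
    n_clones = vapply(res, function(r) length(r$clones), integer(1)),
    error_count = vapply(res, function(r) as.integer(r$error_count), integer(1)),
    decodable = vapply(res, function(r) r$decodable, logical(1)))
  if (!is.null(layout)) {
    ov <- clone_overlaps(layout)
    df$overlap_consistent <- vapply(res, function(r) {
      if (length(r$clones) < 2) return(NA)
      all(vapply(seq_along(r$clones), function(i) {
        all(r$clones[-i] %in% ov[[r$clones[i] + 1L]])
      }, logical(1)))
    }, logical(1))
  }
  h <- table(df$error_count[df$decodable])
  list(assignments = df,
       error_histogram = data.frame(error_count = as.integer(names(h)),
                                    markers = as.integer(h)))
}

#' Simulate pool-level marker calls
#'
#' Plants `n_markers` markers, each carried by a random clone set of size
#' 1..`max_set_size`; the positive pools are the union of those clones'
#' signatures, with 0..`max_flips` uniformly chosen call entries flipped
#' (false positives or negatives).
#'
#' @param design a `pooling_design`.
#' @param n_markers number of markers.
#' @param max_set_size largest planted clone set.
#' @param max_flips maximum flips per marker.
#' @param seed optional integer seed.
#' @return list with `calls` (binary matrix markers x pools), `truth` (list of
#'   0-based clone index vectors) and `flips` (integer vector).
#' @export
simulate_marker_calls <- function(design, n_markers, max_set_size = 3,
                                  max_flips = 3, seed = NULL) {
  stopifnot(inherits(design, "pooling_design"))
  with_seed(seed, {
    calls <- matrix(0L, n_markers, design$n_pools,
                    dimnames = list(paste0("marker_", seq_len(n_markers) - 1),
                                    paste0("pool_", 0:(design$n_pools - 1))))
    truth <- vector("list", n_markers)
    flips <- integer(n_markers)
    for (i in seq_len(n_markers)) {
      sz <- sample.int(max_set_size, 1)
      T <- sort(sample.int(design$n, sz) - 1L)
      truth[[i]] <- T
      S <- unique(as.vector(design$signatures[T + 1L, ]))
      calls[i, S + 1L] <- 1L
      flips[i] <- sample.int(max_flips + 1, 1) - 1L
      if (flips[i] > 0) {
        at <- sample.int(design$n_pools, flips[i])
        calls[i, at] <- 1L - calls[i, at]
      }
    }
    list(calls = calls, truth = truth, flips = flips)
  })
}

#' Read and write marker call matrices
#'
#' TSV with a `marker` column followed by one `pool_<i>` column per pool.
#'
#' @param calls binary matrix as in [decode_markers()].
#' @param path file path.
#' @return `read_opa_calls()` returns the binary matrix with marker rownames.
#' @export
write_opa_calls <- function(calls, path) {
  df <- data.frame(marker = rownames(calls), calls, check.names = FALSE)
  colnames(df) <- c("marker", paste0("pool_", seq_len(ncol(calls)) - 1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_opa_calls
#' @export
read_opa_calls <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (colnames(df)[1] != "marker" ||
      !identical(colnames(df)[-1], paste0("pool_", seq_len(ncol(df) - 1) - 1)))
    stop("format error: expected columns marker, pool_0, pool_1, ...")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$marker
  m
}
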
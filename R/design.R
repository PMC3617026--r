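# Shifted transversal designs and their combinatorial statistics.

is_prime <- function(p) {
  if (p < 2) return(FALSE)
  if (p < 4) return(TRUE)
  if (p %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= p) {
    if (p %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

#' Construct a shifted transversal pooling design
#'
#' Builds the shifted transversal design STD(P, L, Gamma): item i, written in
#' base P as digits \eqn{(i_0, \ldots, i_\Gamma)}, joins in layer j (one layer
#' per shift value j = 0..L-1) the pool
#' \deqn{j P + \left(\sum_{c=0}^{\Gamma} i_c\, j^c \bmod P\right).}
#' Every item is a member of exactly one pool per layer; the L pools holding an
#' item are its *signature*. Any two signatures share at most `gamma` pools,
#' which is what makes pooled sequence decodable back to its source items.
#'
#' @param p prime number of pools per layer.
#' @param layers number of layers L, with `1 <= layers <= p` (the optional
#'   (P+1)-th special layer of the general construction is not supported).
#' @param gamma collision bound \eqn{\Gamma \ge 1}: the maximum number of pools
#'   two signatures may share. The design accommodates up to
#'   \eqn{P^{\Gamma+1}} items.
#' @param n number of items (clones) to pool, `1 <= n <= p^(gamma+1)`.
#' @param clone_ids optional character vector of `n` unique clone labels;
#'   defaults to `"clone_0" ... "clone_<n-1>"`.
#' @return An object of class `pooling_design`: a list with elements `p`,
#'   `layers`, `gamma`, `n`, `n_pools = layers * p`, `clone_ids`, and
#'   `signatures`, an `n x layers` integer matrix of 0-based global pool
#'   indices (row i is the signature of item i-1; column j+1 lies in
#'   `[j*p, (j+1)*p)`).
#' @examples
#' d <- std_design(13, 7, 2, 2197)
#' d$n_pools                     # 91 pools
#' lengths(pool_members(d))[1]   # 169 clones in every pool
#' @seealso [pair_sharing()], [triple_sharing()], [decodability()],
#'   [min_signature_distance()], [write_pool_manifest()]
#' @export
std_design <- function(p, layers, gamma, n = p^(gamma + 1), clone_ids = NULL) {
  p <- as.integer(p); layers <- as.integer(layers); gamma <- as.integer(gamma)
  n <- as.integer(n)
  if (!is_prime(p)) stop("parameter error: P = ", p, " is not prime")
  if (layers < 1 || layers > p)
    stop("parameter error: layers must satisfy 1 <= L <= P, got L = ", layers,
         ", P = ", p)
  if (gamma < 1) stop("parameter error: gamma must be >= 1")
  capacity <- p^(gamma + 1)
  if (n < 1 || n > capacity)
    stop("parameter error: n must satisfy 1 <= n <= P^(gamma+1) = ", capacity,
         ", got n = ", n)
  i <- 0:(n - 1)
  digits <- vapply(0:gamma, function(c) (i %/% p^c) %% p, numeric(n))
  digits <- matrix(digits, nrow = n)
  sig <- vapply(0:(layers - 1), function(j) {
    j * p + as.vector(digits %*% j^(0:gamma)) %% p
  }, numeric(n))
  sig <- matrix(as.integer(sig), nrow = n)
  new_pooling_design(p, layers, gamma, sig, clone_ids)
}

# Low-level constructor shared with the manifest reader.
new_pooling_design <- function(p, layers, gamma, signatures, clone_ids = NULL) {
  n <- nrow(signatures)
  if (is.null(clone_ids)) clone_ids <- paste0("clone_", 0:(n - 1))
  if (anyDuplicated(clone_ids)) stop("clone ids must be unique")
  if (length(clone_ids) != n) stop("clone_ids length must equal n")
  for (j in seq_len(layers)) {
    v <- signatures[, j]
    if (any(v < (j - 1) * p | v >= j * p))
      stop("signature violates layer ranges: layer ", j - 1,
           " entries must lie in [", (j - 1) * p, ", ", j * p, ")")
  }
  rownames(signatures) <- clone_ids
  structure(list(p = p, layers = layers, gamma = gamma, n = n,
                 n_pools = layers * p, clone_ids = clone_ids,
                 signatures = signatures),
            class = "pooling_design")
}

#' @export
print.pooling_design <- function(x, ...) {
  cat("Shifted transversal pooling design\n")
  cat(sprintf("  P = %d pools/layer, L = %d layers, gamma = %d\n",
              x$p, x$layers, x$gamma))
  cat(sprintf("  %d items in %d pools (capacity %d); decodability %d\n",
              x$n, x$n_pools, x$p^(x$gamma + 1), decodability(x)))
  invisible(x)
}

#' @export
summary.pooling_design <- function(object, ...) {
  memb <- lengths(pool_members(object))
  ps <- pair_sharing(object)
  out <- list(design = object, pool_sizes = range(memb), pair_sharing = ps,
              min_distance = if (object$n >= 2) min_signature_distance(object) else NA_integer_,
              decodability = decodability(object))
  class(out) <- "summary.pooling_design"
  out
}

#' @export
print.summary.pooling_design <- function(x, ...) {
  print(x$design)
  cat(sprintf("  pool sizes: %d-%d members\n", x$pool_sizes[1], x$pool_sizes[2]))
  cat("  pairwise signature sharing:\n")
  for (i in seq_len(nrow(x$pair_sharing)))
    cat(sprintf("    %d shared pool(s): %s%%\n", x$pair_sharing$shared[i],
                format_pct(x$pair_sharing$pct[i])))
  cat(sprintf("  min signature distance: %s   decodability: %d\n",
              x$min_distance, x$decodability))
  invisible(x)
}

# One decimal, two for values below 0.1%.
format_pct <- function(p) {
  ifelse(p < 0.1 & p > 0, sprintf("%.2f", p), sprintf("%.1f", p))
}

#' Clone signatures and pool membership
#'
#' `signatures()` returns the `n x L` matrix of 0-based global pool indices;
#' `pool_members()` the transpose view: for each pool, the 0-based item
#' indices it contains.
#'
#' @param design a `pooling_design`.
#' @return `signatures()`: integer matrix; `pool_members()`: list of length
#'   `n_pools` (named by pool index) of integer vectors.
#' @export
signatures <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  design$signatures
}

#' @rdname signatures
#' @export
pool_members <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  items <- rep(0:(design$n - 1), design$layers)
  pools <- factor(as.vector(design$signatures), levels = 0:(design$n_pools - 1))
  out <- split(items, pools)
  names(out) <- 0:(design$n_pools - 1)
  out
}

#' Pairwise signature-sharing histogram
#'
#' Counts, over all unordered pairs of items, how many pools the two
#' signatures share. In a valid shifted transversal design no pair shares more
#' than `gamma` pools.
#'
#' @param design a `pooling_design` with `n >= 2`.
#' @return data.frame with columns `shared` (0..gamma), `pairs` and `pct`
#'   (percentage of all `n(n-1)/2` pairs).
#' @examples
#' pair_sharing(std_design(3, 3, 1, 9))
#' @export
pair_sharing <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  if (design$n < 2) {
    return(data.frame(shared = integer(0), pairs = numeric(0), pct = numeric(0)))
  }
  counts <- .pair_intersection_counts(design$signatures, design$n_pools)
  if (any(counts[(design$gamma + 2):length(counts)] > 0))
    stop("invalid design: a signature pair shares more than gamma pools")
  counts <- counts[1:(design$gamma + 1)]
  data.frame(shared = 0:design$gamma, pairs = counts,
             pct = 100 * counts / sum(counts))
}

#' Triple signature-sharing histogram
#'
#' For a triple of items \{a, b, c\} the shared-pool count is the union
#' deficit \eqn{3L - |sig(a) \cup sig(b) \cup sig(c)|}, i.e. the total number
#' of pool collisions within the triple; it is at most \eqn{3\Gamma}. Either
#' all \eqn{C(n,3)} triples are enumerated or `n_triples` distinct triples are
#' sampled uniformly without replacement (reproducibly for a fixed `seed`).
#'
#' @param design a `pooling_design` with `n >= 3`.
#' @param n_triples number of triples to sample (ignored when `all = TRUE`).
#' @param all enumerate every triple (only feasible for small `n`).
#' @param seed optional integer seed for the sampling; the caller's RNG state
#'   is restored on exit.
#' @return data.frame with columns `shared` (0..3*gamma), `triples`, `pct`.
#' @examples
#' triple_sharing(std_design(3, 3, 1, 9), all = TRUE)
#' @export
triple_sharing <- function(design, n_triples = 1e6, all = FALSE, seed = NULL) {
  stopifnot(inherits(design, "pooling_design"))
  if (design$n < 3) stop("triple statistics require n >= 3")
  if (!all) {
    total <- choose(design$n, 3)
    if (n_triples > total)
      stop("n_triples exceeds the number of distinct triples; use all = TRUE")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  counts <- .triple_deficit_counts(design$signatures, design$n_pools,
                                   n_triples, all)
  if (any(counts[(3 * design$gamma + 2):length(counts)] > 0))
    stop("invalid design: a signature triple shares more than 3*gamma pools")
  counts <- counts[1:(3 * design$gamma + 1)]
  data.frame(shared = 0:(3 * design$gamma), triples = counts,
             pct = 100 * counts / sum(counts))
}

#' Decodability of a design
#'
#' The largest d such that unions of up to d signatures are pairwise distinct
#' when the design is filled to the capacity of its collision bound:
#' \eqn{\lfloor (L-1)/\Gamma \rfloor}. A d-decodable design lets pooled
#' sequence shared by up to d clones be assigned unambiguously.
#'
#' @param design a `pooling_design`.
#' @return a positive integer.
#' @examples
#' decodability(std_design(13, 7, 2, 2197))  # 3
#' @export
decodability <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  as.integer((design$layers - 1) %/% design$gamma)
}

#' Minimum signature distance
#'
#' The minimum, over unordered item pairs, of the symmetric difference of the
#' two signatures: `2 * (L - max pairwise intersection)`. This many pool-level
#' errors are needed before one clone's reads could be mistaken for another's.
#'
#' @param design a `pooling_design` with `n >= 2`.
#' @return an even integer, at least `2 * (L - gamma)`.
#' @examples
#' min_signature_distance(std_design(13, 7, 2, 2197))  # 10
#' @export
min_signature_distance <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  if (design$n < 2) stop("signature distance requires n >= 2")
  ps <- pair_sharing(design)
  maxint <- max(ps$shared[ps$pairs > 0])
  as.integer(2 * (design$layers - maxint))
}
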
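# Pooling manifest I/O: the clone -> layer-pool incidence table as TSV.

#' Write and read a pooling manifest
#'
#' The manifest is a TSV with one row per clone: column `clone_id` followed by
#' L columns `pool_layer_0 ... pool_layer_<L-1>` holding global 0-based pool
#' indices (layer j's column lies in `[j*P, (j+1)*P)`). A leading comment line
#' `# poolkit design P=<p> L=<layers> gamma=<gamma>` records the design
#' parameters, which are not recoverable from the signatures alone.
#'
#' @param design a `pooling_design`.
#' @param path file path.
#' @param clone_ids optional clone labels overriding `design$clone_ids`.
#' @return `write_pool_manifest()` returns `path` invisibly;
#'   `read_pool_manifest()` returns the reconstructed `pooling_design` (the
#'   round trip reproduces signatures and clone ids exactly).
#' @examples
#' d <- std_design(3, 3, 1, 9)
#' f <- tempfile(fileext = ".tsv")
#' write_pool_manifest(d, f)
#' identical(signatures(read_pool_manifest(f)), signatures(d))
#' @export
write_pool_manifest <- function(design, path, clone_ids = NULL) {
  stopifnot(inherits(design, "pooling_design"))
  if (is.null(clone_ids)) clone_ids <- design$clone_ids
  if (length(clone_ids) != design$n) stop("need one clone id per item")
  if (anyDuplicated(clone_ids)) stop("clone ids must be unique")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# poolkit design P=%d L=%d gamma=%d",
                     design$p, design$layers, design$gamma), con)
  df <- data.frame(clone_id = clone_ids, design$signatures,
                   check.names = FALSE)
  colnames(df) <- c("clone_id", paste0("pool_layer_", 0:(design$layers - 1)))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_manifest
#' @export
read_pool_manifest <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first,
                  regexec("^# poolkit design P=(\\d+) L=(\\d+) gamma=(\\d+)$", first))[[1]]
  if (length(m) != 4)
    stop("format error: missing '# poolkit design P=.. L=.. gamma=..' comment line")
  p <- as.integer(m[2]); layers <- as.integer(m[3]); gamma <- as.integer(m[4])
  df <- read.delim(path, skip = 1, check.names = FALSE,
                   colClasses = c("character", rep("integer", layers)))
  expected <- c("clone_id", paste0("pool_layer_", 0:(layers - 1)))
  if (!identical(colnames(df), expected))
    stop("format error: unknown manifest header; expected columns ",
         paste(expected, collapse = ", "))
  sig <- as.matrix(df[, -1, drop = FALSE])
  dimnames(sig) <- NULL
  storage.mode(sig) <- "integer"
  if (any(is.na(sig)) || any(sig < 0) || any(sig >= layers * p))
    stop("format error: pool index outside [0, L*P)")
  new_pooling_design(p, layers, gamma, sig, clone_ids = df$clone_id)
}
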
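# Shared pipeline shorthand for simulation-based tests.

# Simulate pools, build the k-mer table, deconvolute, return everything.
run_pipeline <- function(design, layout, genome, dir, k = 26, outdir = NULL, ...) {
  sim <- sim_pool_reads(design, layout, genome, dir, ...)
  files <- Map(c, sim$files$r1, sim$files$r2)
  table <- kmer_count_table(files, k = k)
  result <- deconvolve_pools(files, table, design, outdir = outdir)
  list(sim = sim, files = files, table = table, result = result,
       truth = read_truth(sim$truth))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
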
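Package: poolkit
Title: Combinatorial Pooling Designs and K-Mer Read Deconvolution for
    Clone-by-Clone Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for selective genome sequencing of clone libraries by
    combinatorial pooling. Constructs shifted transversal designs for pooling
    BAC (or other) clones and reports their combinatorial guarantees, simulates
    pooled paired-end sequencing with a provenance trail, builds per-pool
    canonical k-mer count tables, deconvolutes reads back to their source
    clone(s) by matching count-vector supports against unions of clone
    signatures, scores deconvolution output against simulation truth, and
    decodes binary pool-level marker calls (e.g. GoldenGate assays) to clone
    assignments by error minimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
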
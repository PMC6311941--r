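Package: kernelMDA
Title: Multi-Kernel Link Prediction for miRNA-Disease Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts miRNA-disease associations from a binary association
    matrix and multiple per-side similarity kernels. Builds Gaussian
    interaction profile, sequence-alignment, DAG-semantic and gene-network
    functional similarity kernels; fuses them per side by a
    simplex-constrained least-squares kernel-learning quadratic program;
    denoises the fused kernel with a top-k neighbor sparsifier; and scores
    all pairs by closed-form Laplacian regularized least squares from both
    subspaces. Includes k-fold, global and local leave-one-out
    cross-validation with AUC/AUPR metrics, top-N candidate ranking,
    seeded synthetic-data generators for every input format, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    kernlab,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
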
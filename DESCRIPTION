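Package: lineagemem
Title: Gene Expression Memory and State Switching from Lineage-Barcoded Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying gene expression memory and cell-state
    switching from clonal lineage-barcoded single-cell RNA-seq experiments.
    Recovers transcribed lineage barcodes from reads (anchor search,
    error-correction clustering, cross-sample and oversize filters), scores
    cells against gene signatures with a rank-based statistic, calls
    primed/drug-susceptible/intermediate states, classifies lineages into
    memory categories, and fits a stochastic two-state branching-process
    model (division, death, per-division state switching) to lineage data by
    simulation-based grid inference, including scenario selection for
    treatment effects. A synthetic-data module generates barcode libraries,
    noisy reads, two-state count matrices, and flow-cytometry-like
    intensities so every step can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    mclust,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
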
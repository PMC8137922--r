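Package: atacscreen
Title: Analysis of Single-Cell ATAC-seq CRISPR Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled CRISPR screens with a single-cell chromatin
    accessibility read-out. Assigns sgRNA guides to cell barcodes from
    targeted enrichment reads (1-mismatch barcode matching, count and
    specificity thresholds), builds genome-tile and peak insertion-count
    matrices from 10x-style fragment files with per-cell quality control,
    computes bias-corrected transcription-factor motif accessibility
    deviations against GC- and depth-matched background peaks, refines
    assignments by nearest-neighbour label purity in an LSI embedding on
    differential tiles, ranks perturbation-to-motif effects against
    non-targeting controls, performs peak-level differential accessibility
    with binomial tests and hypergeometric motif enrichment, and contrasts
    TF-TF deviation-score correlation networks between perturbed and
    control cells. Includes a fully seeded synthetic screen generator so
    every stage is testable end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    irlba,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
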
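Package: txrecorder
Title: Transcriptomic Recording Analysis for Live-Cell Biopsy RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell transcriptomic recording
    experiments, in which the ground-state transcriptome of a live cell is
    profiled from a cytoplasmic biopsy and the same cell is then followed by
    time-lapse reporter imaging after stimulation. Provides quality control
    and gene filtering for shallow single-cell count matrices, log
    normalization and variance-stabilized highly variable gene selection,
    log-linear fitting of reporter time courses within a stated response
    window, an unsupervised genome-wide ranking of ground-state genes by
    their ability to predict the per-cell response slope or intercept
    (per-gene linear models with F-tests, bootstrap empirical p-values and
    Benjamini-Hochberg correction), binned-control cell-cycle module scores,
    library-depth-matched count down-sampling, lineage-barcode consensus and
    Hamming matching, and biopsy volume quantification. A seeded synthetic
    data generator with planted gene-phenotype effects makes every stage
    testable without access to external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
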
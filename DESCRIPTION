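Package: scDosage
Title: Chromosome-Wide Dosage Compensation and MSCI Statistics for Germline Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reimplementation of a germline single-cell RNA-seq analysis
    pipeline for detecting dosage compensation and meiotic sex chromosome
    inactivation (MSCI): quality-control filtering of UMI count matrices,
    log-normalisation, PCA and k-means clustering, cluster-versus-rest
    differential expression with enrichment calling, marker-based cell-type
    annotation, centroid-MST pseudotime ordering, and chromosome-class
    expression statistics (X/A and Y/A median log-count ratios with Wilcoxon
    tests and Bonferroni correction, per-cell RNA content by chromosome
    class). Includes a negative-binomial synthetic-data generator that
    emulates the structure of a mosquito testis dataset (ordered germline
    clusters of very unequal size, marker-gene programs, per-cluster
    chromosome-class expression regimes) so that every stage of the pipeline
    can be verified against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
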
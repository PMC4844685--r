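Package: triCell
Title: Cell-Type Attribution of Bulk CNS Expression Changes Using
    Sorted-Cell Reference Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether differential expression observed in
    bulk central-nervous-system tissue reflects transcriptional regulation
    within a cell type or a shift in cellular composition. Implements nRPKM
    normalization (median-of-ratios size factors rescaled to total uniquely
    aligned reads), marker-gene specificity selection, ternary-simplex
    projection of three-cell-type reference profiles, attribution and
    composition-versus-regulation classification of bulk changes,
    fold-change distribution-shift diagnostics, splice-variant frequency
    computation with a replicate-aware differential-usage test, qPCR
    delta-delta-Ct processing with failure imputation, and a negative
    binomial simulator of sorted-cell and mixed bulk experiments with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    rtracklayer
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
biocViews: Transcriptomics, RNASeq, Normalization, GeneExpression,
    AlternativeSplicing, DifferentialExpression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
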
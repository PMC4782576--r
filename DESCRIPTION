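Package: ticmeth
Title: Tissue-Independent and Tissue-Specific DNA Methylation Alterations
    in Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dissecting cancer DNA methylation
    alterations into tissue-independent and tissue-specific components.
    Implements per-sample three-state beta-mixture methylation state
    calling with derived lower/upper thresholds, definition of
    constitutively unmethylated gene promoters and CpG islands and
    constitutively methylated gene bodies from a multi-tissue fetal
    ground state, differential methylation ranking, cross-cancer
    correlation (R squared) analysis, aggregation of histone ChIP-seq
    signals (H3K4me3, H3K27me3, H3K36me3) over promoter windows and gene
    bodies, ROC/AUC and multivariate logistic prediction of cancer
    hyper- and hypomethylation from histone signals in matched normal
    tissue versus embryonic stem cells, and stratification of promoters
    by DNase hypersensitivity and bivalency. Includes a fully seeded
    synthetic-data generator emulating 450k-style beta matrices, histone
    tracks, expression and DHS interval sets, so the whole pipeline is
    testable without consortium downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
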
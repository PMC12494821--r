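Package: statewiseburden
Title: Annotation-State and Repeat-Class Weighted Rare-Variant Burden Tests
    with Sequencing Batch-Effect Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Whole-genome rare and low-frequency variant association testing
    for case-control sequencing studies that combine internally and externally
    sequenced cohorts. Implements beta(MAF,1,25)-weighted burden tests over
    chromatin/conservation annotation states, genomic repeat classes, genes
    (singleton protein-truncating variants) and sliding windows; genomic-control
    lambda inflation diagnostics; sequencing-metadata principal components as
    batch-effect covariates; KING-robust kinship estimation and relatedness
    pruning; LD pruning and genetic PCs; covariate-adjusted logistic single
    variant tests with Firth fallback and exact Fisher tests; permutation-based
    effective-number-of-tests calibration for window scans; and analytic
    case-control power under a multiplicative odds model. Ships a synthetic
    cohort generator that emulates two control cohorts with differential
    sequencing depth and depth-dependent differential variant calling
    concentrated in repeat-like regions, for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
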
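Package: pairedCNA
Title: Paired Copy-Number Comparison of Primary Tumours and Lymph-Node Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for array-CGH copy-number comparison of paired
    primary breast tumours and lymph-node metastases. Provides Gaussian
    kernel-convolution smoothing of probe-level log2 ratios, correlation-distance
    average-linkage clustering with matched-pair concordance scoring, a paired
    permutation test for recurrent regional copy-number differences between
    groups, circular binary segmentation with a standard-deviation breakpoint
    undo rule, and the pairwise "delta-profile" analysis (per-pair quantile
    normalization, subtraction, segmentation, segment counting, subtype
    comparison and recurrent-overlap search). Includes a synthetic paired-cohort
    generator with ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    limma,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
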
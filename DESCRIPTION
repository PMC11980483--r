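Package: photorank
Title: Rank-Sum Screening for Contrasting Photoperiod Responses in
    RNA-Seq Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies genes with opposite photoperiod responses between two
    genotypes of differing photoperiodic requirement from gene-by-sample count
    matrices. Provides per-time-point long-day versus short-day differential
    expression (median-of-ratios normalization, method-of-moments negative
    binomial dispersion, Wald test, Benjamini-Hochberg FDR), direction-aware
    log fold-change ranking with a cross-genotype rank-sum contrast score,
    expression-level and replicate-variability filters, morning/afternoon
    candidate-set union accounting, and a negative binomial count simulator
    with planted gene classes for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
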
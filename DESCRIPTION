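Package: mirlogr
Title: Deleteriousness Prediction and Annotation of Human microRNA Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to score the deleteriousness of single-nucleotide variants
    in human microRNA hairpins. Implements a meta-predictor that combines ten
    precomputed noncoding-variant scores through iterative missing-score
    imputation, principal-component decorrelation, quadratic polynomial
    feature expansion and imbalance-aware bagging of L2-regularized logistic
    regressions. Also provides microRNA hairpin anatomy annotation
    (seed, mature, loop and out-of-loop subregions), exhaustive allelic SNV
    enumeration with HGVS-style naming, population-variability statistics
    (SNV density, transition/transversion spectra, allele-frequency spectra,
    coverage rules), and synthetic-data generators that emulate every input
    format so the full pipeline can be exercised without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    glmnet,
    IRanges,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
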
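Package: dosagemeta
Title: Cross-Platform Meta-Analysis of Gene-Dosage Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signed, sample-size-weighted Z-score meta-analysis of case/control
    gene-expression studies across microarray and RNA-seq platforms, with
    heterogeneity filtering and hypergeometric over-representation analysis,
    motivated by trisomy-21 gene-dosage studies in induced pluripotent stem
    cells. Includes per-study differential-expression engines (empirical-Bayes
    moderated t for log-intensity arrays, negative-binomial likelihood-ratio
    test for counts), probe-to-symbol harmonization, a multi-platform
    synthetic-data generator with known ground truth, and closed-form utilities
    for mitochondrial functional assays (Fura-2 ratiometric calcium
    calibration, Seahorse-style oxygen-consumption respiratory indices,
    percent-of-control normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    edgeR,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
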
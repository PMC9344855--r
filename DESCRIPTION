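Package: coexmi
Title: Threshold-Free Marker Co-Expression Analysis for Multiplex Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies co-expression of two or more markers in segmented
    multiplex-imaging data (mIHC, MIBI, imaging mass cytometry) without
    positivity thresholds, using the standardized Euclidean quadratic mutual
    information (EQMI*) between cell-level marker intensities.  Per-subject
    EQMI* vectors are tested for association with continuous, binary or
    right-censored clinical outcomes (linear Wald, logistic, Cox
    likelihood-ratio tests), with an exhaustive marker-combination scan and
    per-size Bonferroni correction.  Includes the traditional
    quantile-thresholding/hierarchical-clustering pipeline and the absolute
    Pearson correlation as comparator methods, Gaussian-copula and
    deterministic nonlinear simulators of cell-level intensity data, and an
    empirical-power engine comparing all methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
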
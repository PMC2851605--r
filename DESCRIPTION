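Package: i2r
Title: Indirect Two-Sided Relative Ranking for Gene Expression Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Signature-based similarity search for gene expression profiles
    that is robust to experimental confounders such as delivery vehicle and
    processing batch. Implements the two-sided truncated Kolmogorov-Smirnov
    (connectivity-map style) direct score between a query signature and a
    ranked probe list, and the indirect two-sided relative ranking (I2R)
    score: the Spearman rank correlation between two instances' vectors of
    direct scores against every instance in the database. Includes retrieval
    evaluation across vehicle/batch barriers (recall at rank k, percent
    improvement, positive predictive value), majority-vote classification,
    average-rank and paired t-test comparisons, ROC/AUC with DeLong tests,
    a permutation test for set-level significance, and a generator of
    synthetic confounded expression databases with known class structure.
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
    purrr,
    pROC,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
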
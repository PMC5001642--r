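Package: crosstesting
Title: Data-Efficient Evaluation Schemes for Supervised Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements three data-partitioning schemes for estimating the
    generalization accuracy of a supervised two-class classifier:
    cross-validation followed by testing on a held-out set, nested
    cross-validation, and cross-validation followed by cross-testing, in which
    the held-out test set is itself k-fold partitioned and each fold is scored
    by a model trained on the cross-validation set plus the remaining test
    folds.  Cross-testing re-uses held-out data for model fitting without
    scoring any sample by a model that saw it, so the selected preprocessing
    and penalty parameters stay interpretable while accuracy estimates improve.
    Includes a permutation test of accuracy against chance with a randomized
    decision rule that keeps the test at its exact nominal size despite the
    discreteness of the permutation null, synthetic benchmark data generators
    (a linearly inseparable two-class design and a random-label null design),
    and Monte-Carlo sweep drivers over data-set size and test-set fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
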
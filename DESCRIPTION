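Package: wrhfs
Title: Weighting- and Ranking-Based Hybrid Feature Selection for Clinical
    Risk Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements weighting- and ranking-based hybrid feature
    selection (WRHFS) for binary clinical risk detection on complete
    numeric feature tables. Filter scorers (standard deviation, Pearson
    correlation, Fisher score, information gain, Relief, chi-squared test)
    rank features; a cross-validated, grid-tuned RBF support vector
    machine converts each ranking into a prefix-accuracy curve and
    per-feature accuracy contributions; a voting and assessment stage
    aggregates the best three filter models into a single feature
    weighting, a top-N feature subset, and a synthetic-value risk index
    with a banded risk surface. Ships the reference weighting tables from
    the original ischemic-stroke application as fixtures, diagnostic
    metrics (sensitivity, specificity, accuracy, Youden index), a
    synthetic-cohort generator with planted informative features, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rpart,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
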
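Package: wisfc
Title: Consensus Feature-Importance Ranking Across Diverse Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates feature-importance rankings from an ensemble of
    heterogeneous machine-learning models into a single consensus ranking
    using two complementary metrics: a Weighted Importance Score (WIS), the
    optionally performance-weighted average of each feature's normalized
    importance, and a Frequency Count (FC), the fraction of models placing
    the feature in their top-k list. Includes a brute-force model harness
    (logistic/linear regression, decision tree, random forest, gradient
    boosting, kernel SVM) with cross-validated performance and per-model
    importance extraction, a synthetic tabular-cohort generator with planted
    informative features for recovery testing, and a bootstrap stability
    evaluator comparing top-k set stability of the consensus ranking against
    single models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    rpart,
    ranger,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
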
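Package: drugrankr
Title: Positive-Unlabelled Ensemble Ranking of Gene Druggability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores every gene in a gene-by-feature table for druggability
    with a stochastic semi-supervised positive-unlabelled ensemble: known
    drug-target genes are paired with random balanced subsets of the
    unlabelled exome, classifiers are trained under stratified k-fold
    cross-validation, and out-of-bag probabilities are averaged into a
    per-gene druggability score.  Includes automated feature
    pre-processing (correlation pruning, sparsity filtering, class-aware
    imputation, standardisation), protein-protein interaction network
    feature engineering (seed-overlap ratios at one and two hops),
    Boruta shadow-feature selection, gradient-boosting hyperparameter
    tuning, enrichment-based validation statistics (Fisher exact tests
    over rank intervals, DeLong AUC comparison, stepwise hypergeometric
    curves), and seeded synthetic-data generators for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    ranger,
    xgboost,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
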
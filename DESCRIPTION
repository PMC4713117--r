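Package: gaeoc
Title: Genetic-Algorithm Search for Heterogeneous Ensembles of Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects a subset of a heterogeneous base-classifier pool that
    maximises the mean Matthews correlation coefficient (MCC) of an
    unweighted majority-vote ensemble under 10-fold cross-validation, using
    a genetic algorithm over bitmask-encoded ensembles (tournament
    selection, uniform crossover, random-bit-replacement mutation,
    elitism). Includes class-distribution balancing for imbalanced
    two-class data by partitioning the majority class into minority-sized
    chunks, supervised entropy/MDL discretization with feature filtering,
    (alpha,beta)-k minimum feature-set selection with union/intersection
    consolidation, one-vs-all decomposition of multiclass problems, cached
    per-fold model stores, a repeated-runs evaluation protocol and
    synthetic generators with exhaustively certified optima for testing
    the search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    foreign,
    e1071,
    rpart,
    randomForest,
    ranger,
    class,
    nnet,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
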
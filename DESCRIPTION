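Package: deqsar
Title: Desirability-Based Ensemble QSAR Models for Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds per-cell-line QSAR classifiers from assay activity tables and
    combines them into multi-objective ensembles ranked by a geometric-mean
    desirability score. Covers activity-table curation (structure standardization,
    10 uM activity thresholding with a strict 75 percent majority rule,
    deduplication), 2D substructural fragment descriptors (atom/bond sequences,
    atom-centered fragments, topological triplets), frequency filtering and
    mRMR/MIQ feature ranking, Ward-clustering-stratified class balancing,
    genetic-algorithm wrapper feature selection with bootstrap BCR fitness over
    six learner families, exhaustive desirability-ensemble combination search,
    and early-recognition evaluation of ranked screening lists (AUC, enrichment
    factor, BEDROC with a numerically solved alpha). Includes a synthetic-study
    generator (valence-valid molecule libraries with planted substructure-driven
    activity and property-matched decoys) for end-to-end validation without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    class,
    e1071,
    jsonlite,
    methods,
    nnet,
    randomForest,
    rpart,
    stats,
    tools,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
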
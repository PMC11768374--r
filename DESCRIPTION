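Package: StackScreen
Title: Stacked Ligand- and Structure-Based Virtual Screening for Kinase Inhibitor Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A target-agnostic drug-repurposing pipeline for kinase inhibitors.
    Ingests compound activity tables and screening libraries, groups inhibitors by
    most-central-ring scaffold and computes potency-association statistics and
    enrichment factors, fits descriptor-based QSAR regression models with a
    three-method applicability domain, classifies compounds from pharmacophore
    pattern-count fingerprints reduced to principal components, stacks the stage
    outputs in an L2-regularised logistic meta-model, and rescores docking results
    with interaction-fingerprint screening metrics and a multilayer-perceptron
    classifier. Seeded synthetic generators emulate every pipeline input so all
    stages are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    igraph,
    e1071,
    randomForest,
    xgboost,
    glmnet,
    caret,
    mixOmics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
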
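Package: pharmboost
Title: Pharmacophore-Pair Interaction Fingerprints and Boosted SVM
    Ensembles for Structure-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes protein-ligand complexes into Pharm-IF interaction
    fingerprints (pairs of ligand pharmacophore features in contact with the
    protein, soft-binned by their mutual distance) and ranks screening
    compounds with an AdaBoost ensemble of case-weighted RBF support vector
    machines designed to tolerate label noise from incorrect docking poses.
    Includes plain SVM and Random Forest baselines, enrichment-factor and
    ROC/AUC screening metrics, a synthetic benchmark generator with a
    wrong-pose label-noise process, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
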
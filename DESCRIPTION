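Package: aifp
Title: Atomic Interaction Fingerprints and Pharmacology Classification for
    Docked Receptor-Ligand Poses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Types receptor-ligand atomic contacts from 3D docking poses into
    an interaction-subtype taxonomy using distance and angle rules, filters
    poses on binding-pocket anchor interactions, encodes poses into binary
    interaction matrices, ranks interaction features by correlation with
    pharmacological action, trains and evaluates tree-ensemble classifiers of
    agonism versus antagonism (Matthews correlation coefficient, repeated
    stratified k-fold cross-validation, bootstrap confidence intervals), and
    attributes predictions to individual interactions with exact and
    tree-structured Shapley values. Ships synthetic-data generators (toy
    binding pockets and planted-signal fingerprint matrices) so the whole
    pipeline is testable without docking runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    data.table,
    jsonlite,
    lhs,
    methods,
    ranger,
    Rcpp,
    stats,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
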
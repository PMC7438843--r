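Package: bvote
Title: Ensemble Prediction of Incident Bacterial Vaginosis from the
    Penile Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for predicting incident bacterial vaginosis (BV) in
    women from their male partner's baseline penile microbiome profile.
    Implements compositional preprocessing of 16S taxa count tables
    (prevalence filtering, uniform zero replacement, centered log-ratio
    transform, min-max normalization), SMOTE rebalancing of the incident-BV
    minority class, a majority-voting ensemble of random forest, RBF support
    vector machine and k-nearest-neighbour classifiers evaluated by repeated
    stratified cross-validation, rank-averaged ensemble variable importance,
    and a permutation t-test for comparing AUC distributions between
    sampling sites. Includes a Dirichlet-multinomial synthetic couples-cohort
    generator with longitudinal Nugent scores so the full pipeline can be
    exercised and calibrated without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ranger,
    e1071,
    class,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
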
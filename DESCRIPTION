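Package: aurqsar
Title: Imbalance-Aware QSAR Modelling of Thyroperoxidase Inhibition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and validates binary quantitative structure-activity
    relationship (QSAR) classifiers for thyroperoxidase (TPO) inhibition
    measured with the Amplex UltraRed (AUR-TPO) assay. Covers the full
    workflow: SMILES curation (salt neutralization, element filtering,
    tautomer-aware deduplication), selectivity-based hit-call
    stratification (INA/NSE/LSE/HSE), descriptor pruning and scaling,
    Gini- and permutation-importance feature ranking with subset-size
    sweeps, class rebalancing by SMOTE oversampling or balanced
    random-forest undersampling, model tuning in stratified
    cross-validation scored by balanced accuracy, and evaluation through
    Cooper's statistics, the Matthews correlation coefficient,
    Y-scrambling, probability-threshold applicability-domain curves and
    two-model unanimity consensus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    optparse,
    withr
Config/testthat/edition: 3
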
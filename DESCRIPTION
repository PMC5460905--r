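Package: mtqsar
Title: Multi-Target QSAR Modelling of Chemical-Protein Interactions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ligand-based multi-target QSAR modelling for chemical-protein
    interaction (CPI) prediction. Builds per-target binary classifiers
    (Laplacian-corrected naive Bayes and recursive-partitioning decision
    trees) over circular (ECFP-style) and 166-key structural fingerprints,
    evaluates them by stratified k-fold cross-validation and external test
    sets (sensitivity, specificity, accuracy, Matthews correlation
    coefficient, ROC AUC), combines the four per-target classifiers into a
    2-of-4 consensus interaction call, and analyses the resulting
    compound-target-mechanism networks. Includes compound standardization
    (salt stripping, deduplication, activity labelling), decoy sampling,
    a synthetic benchmark generator with planted scaffolds, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    ChemmineR,
    ChemmineOB
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
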
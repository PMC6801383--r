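Package: molsnap
Title: Image-Based QSAR from Omnidirectional 3D Molecular Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds image datasets for quantitative structure-activity
    relationship (QSAR) modelling by rendering small molecules as 3D
    ball-and-stick snapshots photographed over a grid of x/y/z rotations.
    Provides activity-table curation and labeling for high-throughput
    screening data, structure washing (protonation adjustment and seeded
    3D conformer generation), a deterministic ball-and-stick renderer with
    distance-based bond perception, molecule-level train/validation/test
    splitting with permutation controls, a pluggable image-classifier
    contract with a small reference convolutional network, a
    descriptor-table tree-ensemble baseline, and an evaluation suite with
    per-molecule median aggregation, ROC/AUC, Youden cutoff selection and
    balanced-accuracy/MCC metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    png,
    Matrix,
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
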
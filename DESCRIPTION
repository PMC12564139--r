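Package: densCT
Title: Two-Stage Dens Fracture Detection Pipelines for CT Volumes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying segmentation-then-classification pipelines for
    odontoid (dens axis) fracture detection in computed tomography. Provides a
    seeded 3D bone-phantom generator, NIfTI volume handling with isotropic
    resampling, five Hounsfield-unit windowing / contrast-adjustment methods
    (bone window, gamma-corrected bone window, histogram-based, CLAHE and
    ROI-based percentile windowing), from-scratch radiomics feature extraction
    (first-order, shape, gray-level co-occurrence texture), small CPU-trainable
    convolutional networks for direct classification and for dens segmentation,
    six classical machine-learning classifiers over radiomic features, Dice
    similarity analysis with DSC-targeted mask perturbation, and an experiment
    layer that evaluates classification stability across controlled
    segmentation-quality levels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    RNifti,
    EBImage,
    igraph,
    rpart,
    ranger,
    xgboost,
    class,
    e1071,
    randomForest,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
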
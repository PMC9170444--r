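Package: ikfcm
Title: Intuitionistic Kernel Fuzzy C-Means Segmentation of Brain MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fuzzy C-means (FCM) tissue segmentation for brain magnetic
    resonance images, together with an improved variant that combines
    intuitionistic fuzzification (membership, non-membership and hesitation
    degrees per voxel), a Gaussian-kernel-induced distance, spatial
    neighborhood regularization, and a hesitation-degree correction of the
    membership matrix.  Includes cluster-validity indices (partition
    coefficient, partition entropy, Xie-Beni), a spin-echo phantom simulator
    with ground-truth labels, segmentation evaluation (volumetry, label
    matching, confusion-matrix metrics), two-group biomarker statistics with
    ROC/AUC and Youden-optimal cutoffs, NIfTI input/output, brain-mask
    extraction, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
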
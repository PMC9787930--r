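Package: kbfmgmt
Title: Knowledge-Based Tumor ROI Preselection and Compact CNNs for MGMT
    Promoter Methylation Identification in Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying MGMT promoter methylation
    status from paired FLAIR and T1-weighted brain MRI. Volumes are
    reconstructed from DICOM series, resampled to 1 mm isotropic resolution,
    reoriented to a sagittal standard and skull-stripped; an unsupervised
    multimodal knowledge-based filter (mode split, 25 percent tail quantiles
    and cross-intersection of FLAIR-bright and T1-dark voxels) preselects
    suspicious tumor regions; a compact 2D/3D convolutional network built from
    depthwise-separable blocks classifies the masked, cropped and normalized
    FLAIR volume; stratified k-fold cross-validation, rank-based AUC and
    confusion-matrix metrics evaluate it; integrated gradients and occlusion
    maps explain it. A seeded synthetic brain-phantom generator makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
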
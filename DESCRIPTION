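Package: lesionshape
Title: Form-Factor Shape Biomarkers for 3D Lesion Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-dimensional morphological analysis of binary lesion
    segmentation masks for benign-versus-malignant screening. Computes
    eleven shape features per lesion (maximum 3D diameter, mesh surface
    area, voxel volume, the Angelidakis elongation/flatness/compactness
    decomposition, Kong elongation and flatness, maximum projection
    sphericity, sphericity, and bounding-box volume density) from the
    axis-aligned bounding box and a marching-tetrahedra isosurface of the
    mask; screens features with Mann-Whitney U tests under
    Benjamini-Hochberg false-discovery-rate control; evaluates linear
    support-vector-machine models with per-dataset Z-scoring,
    leave-one-out and cross-dataset validation; and estimates
    accuracy-maximising univariate cutoff thresholds. Includes geometric
    voxel phantoms with closed-form oracles and moment-matched synthetic
    cohorts so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    e1071,
    tibble,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
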
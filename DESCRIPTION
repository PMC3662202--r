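Package: ventmorph
Title: Ventricular Morphometry and MRI-Based Classification of
    Alzheimer's Disease and Mild Cognitive Impairment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-analysis and classification pipeline for
    discriminating Alzheimer's disease (AD) and mild cognitive
    impairment (MCI) from normal controls (NC) using structural brain
    MRI. Provides seeded synthetic brain phantoms with group-dependent
    ventricular geometry; Gaussian-mixture tissue segmentation into
    gray matter, white matter and cerebrospinal fluid with voxel-count
    volumetry; ventricle extraction by double-threshold region growing
    with morphological cleanup and slice-wise Sobel edges; 3D
    probability/discriminate maps with a matching coefficient, and 17
    two-dimensional shape descriptors computed on the maximum-area
    datum slice; Mann-Whitney U feature screening and principal
    component analysis on the correlation matrix; and three
    classifiers - a two-stage self-organizing map, a one-against-rest
    soft-margin RBF support vector machine solved by sequential minimal
    optimization, and a particle-swarm-optimized SVM - evaluated under
    leave-one-out cross-validation with confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab,
    optparse
Config/testthat/edition: 3
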
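Package: tibiassm
Title: Statistical Shape Modelling of Longitudinal Cortical Bone MicroCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies three-dimensional geometric effects of treatment on
    long-bone midshaft sections from longitudinal binarized volumetric
    images. Provides grid-parameterized deformable image registration with
    trilinear displacement interpolation, binarization and topological
    geometry correction of cortical sections, labeled endosteal/periosteal
    surface extraction and coarsening, PCA shape decomposition with
    leave-one-out validation, and nonparametric categorization of shape
    modes into treatment effects with effect sizes and median surface-change
    fields. Includes a synthetic midshaft phantom generator and a
    virtual-displacement validation harness for registration accuracy and
    precision.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
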
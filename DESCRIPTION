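Package: GaborDictSeg
Title: Patch-Based 3D Liver CT Segmentation with Gabor Sparse Dictionaries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Atlas-prior, patch-based segmentation of the liver in 3D CT
    volumes. A gold-standard mask is warped into the target volume by a
    landmark-driven B-spline deformation; patches sampled on the warped prior
    boundary are described by Gabor filter-bank texture features; a K-SVD
    dictionary trained on gold-standard boundary patches scores candidate
    boundary locations by their orthogonal-matching-pursuit reconstruction
    error; the selected boundary point cloud is repaired into a watertight
    surface and solid mask by octree parity labelling and dual contouring.
    Includes the MICCAI 2007 evaluation metric suite (VOE, RVD, ASSD,
    RMSSSD, MSSD), a synthetic phantom generator, and an end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    EBImage,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'registration.R'
    'sparse-dictionary.R'
    'gabor.R'
    'boundary.R'
    'evaluation.R'
    'phantom.R'
    'void-filling.R'
    'pipeline.R'
    'volume-io.R'
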
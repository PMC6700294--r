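Package: anisoseg
Title: Cascaded Anisotropic Networks for Brain Tumor Segmentation with
    Test-Time-Augmentation Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hierarchical segmentation of brain tumor subregions (whole
    tumor, tumor core, enhancing core) from multi-modal MRI with a cascade
    of anisotropic 2.5D convolutional networks (WNet, TNet, ENet), built on
    a small native tensor backend.  Provides declarative network blueprints
    with analytic and probed receptive fields, multi-view fusion,
    Monte-Carlo test-time augmentation with majority voting, voxel-wise
    entropy and structure-wise volume-variation-coefficient uncertainty,
    uncertainty-aware dense-CRF post-processing, Dice/Hausdorff evaluation,
    and a synthetic multi-modal phantom generator so the full pipeline can
    be exercised end-to-end without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
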
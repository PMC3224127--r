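Package: multiseg
Title: Simultaneous Segmentation of Multiple Touching Objects with
    Deformable Simplex Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic segmentation of N similar, touching objects in a
    3-D scalar volume using deformable simplex meshes. Initial spheres placed
    at user seed points are inflated by a balloon force gated on a supervised
    Bayesian (object versus background) voxel classification, attracted to
    boundaries by gradient and edge forces, kept apart by a collision force
    built from XOR-combined binary masks of the other meshes, and confined to
    a histogram-derived container ("tube") mask. Deformation is staged from
    coarse to fine mesh resolution and each object is emitted as a binary
    NIfTI mask. Includes a synthetic phantom generator (gel-filled tube with
    touching ellipsoids, bias field and noise) and the validation metrics
    (Cohen's kappa, specificity, accuracy, Dice).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
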
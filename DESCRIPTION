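Package: osteofe
Title: Voxel-Based Micro-Finite-Element Analysis of Cortical Bone Defects and
    Bioactive Glass Grafts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based micro-finite-element (muFE) tools for quantifying how
    cortical-window defects weaken long bones and how implanted bioactive-glass
    (BAG) granule and bone-morsel grafts restore stiffness and share load.
    Provides synthetic phantom generators (long-bone diaphyses, distal-tibia
    segments, granule/morsel mixture beds, beam-hardening artifacts), threshold
    segmentation with morphological interface-layer construction, voxel-to-
    hexahedron meshing with bending and compression boundary conditions, a
    matrix-free preconditioned conjugate-gradient linear elasticity solver,
    virtual osteotomy and graft implantation, and outcome analyses: bending and
    axial stiffness, Pistoia strain-criterion failure moments, paired
    maintained/reduction fractions, per-phase load sharing, and material-
    property fitting against confined-compression aggregate moduli.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
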
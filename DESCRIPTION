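Package: metcad
Title: Computer-Aided Detection of Brain Metastases on 3D MR Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete computer-aided detection (CAD) pipeline for
    contrast-enhancing brain metastases on 3D T1-weighted MR volumes:
    seed-anchored intensity normalization, spherical-based seed region
    growing (SSRG) brain extraction, dual-branch lesion candidate
    detection (3D normalized cross-correlation template matching for
    small spheroid nodules plus K-means intensity clustering for large
    or irregular lesions), a 30-feature radiomic descriptor (histogram
    moments, box-counting fractal dimension, GLCM and GLRLM texture),
    an artificial neural network for false-positive reduction, and
    FROC / JAFROC figure-of-merit evaluation.  A seeded synthetic
    head-phantom generator with known nodule ground truth makes the
    whole pipeline testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
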
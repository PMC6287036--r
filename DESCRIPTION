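Package: ecgpose
Title: Beat-by-Beat Tracking of Heart Position and Orientation from
    Electrocardiographic Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the rigid position and orientation of the heart inside
    the torso for every heartbeat from simultaneous heart-surface and
    body-surface potential recordings. The electrocardiographic forward model
    (a boundary element method volume conductor) is parameterized by a
    six-dimensional rigid pose and fitted per beat by bound-constrained
    nonlinear least squares, with box constraints that prevent the heart from
    intersecting the torso surface. Includes mesh geometry utilities (OFF and
    ASCII VTK readers and writers, watertightness and intersection tests), the
    linear-collocation BEM transfer-matrix solver, a zero-order Tikhonov
    inverse with L-curve regularization selection, evaluation metrics, and a
    synthetic respiratory-motion experiment generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
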
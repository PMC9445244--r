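Package: strucage
Title: Structure-Level Brain Age from Surface Meshes with Spectral Graph
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the biological "age" of individual brain structures
    from template-registered triangulated surface meshes. Meshes are
    converted to graphs, coarsened by multiscale binary partitioning so that
    stride-2 pooling is valid, and fed to a residual Chebyshev
    graph-convolutional network with a learnable soft-bin age head. Includes
    ensemble and test-time-augmentation inference, LOWESS/smoothing-spline
    prediction-bias correction, cross-sectional and longitudinal
    (mixed-model) analyses of structure age by diagnostic group, and a
    synthetic mesh/cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
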
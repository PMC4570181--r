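Package: otrecon
Title: Sparse Source Reconstruction for Diffuse Optical Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for reconstructing internal light-source distributions
    (bioluminescence, fluorescence and Cerenkov luminescence tomography)
    from boundary optical measurements. Provides a finite-element forward
    model of the diffusion approximation on labeled tetrahedral meshes, a
    deterministic heterogeneous cylinder phantom generator with tissue
    optical-property presets, boundary detector modeling, and three inverse
    solvers for the ill-posed linear system: a linearized Bregman iteration
    with l1 sparsity regularization, Tikhonov regularization by conjugate
    gradients, and a Split Bregman l1 solver. Includes localization and
    contrast-to-noise evaluation metrics, permissible-source-region
    restriction, and file-based simulate/reconstruct/evaluate pipelines.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    graphics,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
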
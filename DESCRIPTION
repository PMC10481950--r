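Package: organmotion
Title: Probabilistic Diffeomorphic Modelling of Inter-Fraction Pelvic Organ Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling of day-to-day anatomical change in pelvic
    radiotherapy. Given a planning image and organ label map, a conditional
    latent-variable model produces stationary velocity fields that are
    exponentiated (scaling and squaring) into diffeomorphic deformation
    vector fields and used to warp the planning anatomy into plausible
    repeat anatomies. Includes the full training objective (local normalized
    cross-correlation likelihood, soft multi-organ DICE, spatial gradient
    regularisation, KL divergence), hand-written 3D convolutional networks
    with exact reverse-mode gradients, a synthetic pelvic phantom population
    generator with known ground-truth deformations, evaluation procedures
    (reconstruction accuracy, generative distribution recovery, latent
    traversal and latent-space structure), NIfTI I/O and a command line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tools,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
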
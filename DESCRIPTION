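Package: octvae
Title: Predicting Postoperative Macular OCT B-Scans with a Conditional
    Variational Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for predicting 6-month postoperative macular
    optical coherence tomography (OCT) B-scans from preoperative volume scans
    after full-thickness macular hole surgery. Provides synthetic layered
    retinal phantoms with known ground truth, lossless volumetric TIFF input
    and output, retinal-pigment-epithelium based rigid volume registration by
    orthogonal Procrustes, conditioned preprocessing and augmentation of
    fovea-centered slice pairs, a conditional variational autoencoder trained
    with a binary cross-entropy plus multi-scale structural similarity
    reconstruction loss, KLD warm-up and a late perceptual-loss phase, and a
    quantitative agreement suite (neurosensory-area concordance, retinal
    thickness profiles, percentage Bland-Altman limits of agreement, and
    ELM/EZ band continuity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
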
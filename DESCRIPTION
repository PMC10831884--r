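Package: bolddecode
Title: Decoding Visual Stimuli from fMRI Through a Shared Latent Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing naturalistic video stimuli from BOLD
    fMRI responses. A recurrent convolutional autoencoder learns a latent
    space for video frames; a gated recurrent map projects region-of-interest
    voxel time series into the same space, so that fMRI frames can be decoded
    back to images. Includes a synthetic paired (video, fMRI) data generator
    with a double-gamma haemodynamic forward model, global signal regression
    and data-driven ROI selection, cluster-structure evaluation via the
    adjusted Rand index, nearest-neighbour stimulus matching, object-label
    overlap scoring, and face-detection ROC analysis, together with a
    leave-one-clip-out cross-validation pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    png,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
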
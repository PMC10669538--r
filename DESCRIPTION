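Package: clickseg
Title: Training-Free Click-Seeded Interactive Segmentation for Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interactive segmentation of 2-D grayscale medical images (CT/MRI
    slices) from single user clicks, without any segmentation training data.
    A click is grown into an organ mask by iteratively blending the image with
    the current mask in the latent space of a VGG19-style convolutional
    autoencoder: kernel-density intensity remapping suppresses tissue unlike
    the clicked organ, feature-space averaging against a black reference
    isolates the mask-induced brightening, and Otsu thresholding binarizes the
    result until a fixed point is reached. Positive and negative refinement
    clicks grow or carve the mask via click-centered Gaussian density
    competition. Includes a CT-like phantom generator with ground-truth masks,
    a trainable fixture autoencoder, and a simulated-click Dice-per-click
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    RNifti,
    jsonlite,
    png,
    rlang,
    stats,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
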
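Package: egan3d
Title: Separable-Convolution 3D Adversarial Translation of FDG-PET to T1 MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-modality translation of volumetric FDG-PET into T1-weighted
    MRI with a conditional generative adversarial network built from a
    separable-convolution per-view encoder, a tanh-normalized Hadamard fusion
    of the three anatomical view feature maps, a fixed 3x3x3 Sobel edge
    channel, a 3D convolutional decoder and a 3D fully convolutional
    discriminator, trained with a weighted hybrid adversarial + L2 objective.
    Ships the full intrinsic evaluation suite (PSNR, SSIM, MAE, normalized
    cross-correlation, 3D grey-level co-occurrence Haralick texture features,
    three-class tissue analysis) and a paired ellipsoid head-phantom generator
    so training and evaluation run at desk scale without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
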
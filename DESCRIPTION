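Package: msssl
Title: Multi-Scale Self-Supervised Pretraining for Diabetic Retinopathy Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Saliency-guided, green-channel, momentum-encoder self-supervised
    pretraining for color fundus photographs, built around a multi-scale
    encoder that fuses a vision-transformer global branch with a
    ResNet/feature-pyramid fine-grained branch, refined by a transposed-
    convolution Deep Learner module with convolutional block attention.
    Includes fundus-specific preprocessing (green-channel extraction,
    border cropping, spectral-residual and fine-grained saliency with Otsu
    binarization), SimCLR-style two-view augmentation, the joint
    representation-matching plus segmentation pretraining objective,
    downstream linear-evaluation and fine-tuning protocols with ordinal
    grading metrics (quadratic weighted kappa, weighted/macro/micro F1),
    attention-map visualization, and a synthetic fundus-image generator so
    the whole pipeline runs at desk scale without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
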
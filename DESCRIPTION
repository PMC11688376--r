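Package: sacmetry
Title: Gestational Sac Biometry and Segmentation Evaluation for Early-Pregnancy Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated biometry of the gestational sac in early-pregnancy
    ultrasound: Moore neighbor boundary tracing of binary segmentation masks,
    minimum-area enclosing rectangle fitting by rotating calipers, pixel-spacing
    scaled diameter measurement, and gestational age estimation with the Hellman
    mean-sac-diameter formula. Also provides segmentation losses (Dice, Jaccard,
    binary cross-entropy), region overlap metrics (IoU, Dice, Recall, Precision),
    consensus ground-truth construction, Bland-Altman agreement analysis, a
    desk-scale convolutional segmentation model zoo (UNet, UNet++, DeepLabV3,
    ResUNet with a ResNet50 encoder) with exact trainable-parameter accounting,
    an augmentation and stratified cross-validation protocol, and a synthetic
    sac-phantom generator with analytically known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
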
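Package: mammoseg
Title: Connected U-Net Architectures for Breast Mass Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains, and evaluates encoder-decoder networks for
    segmenting breast mass lesions in mammogram regions of interest (ROIs):
    the standard and "connected" (cascaded, cross-linked) variants of U-Net,
    Attention U-Net, and Residual U-Net, each with an atrous spatial pyramid
    pooling (ASPP) transition block. Includes a weighted Dice/IoU
    segmentation loss, pixel-wise ROC/AUC evaluation, an IoU_90-based
    end-to-end accuracy measure, a largest-component mask cleanup, the full
    data-preparation recipe (resizing, histogram equalization, six-fold
    rotation/CLAHE augmentation, 70/20/10 partitioning), and a seedable
    generator of mammogram-like lesion phantoms with paired ground-truth
    masks so the whole pipeline is exercisable offline. The network
    forward/backward passes and the Adam optimizer are implemented natively
    on BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
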
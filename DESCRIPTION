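Package: octskin
Title: Contour-Aware Semisupervised Segmentation of Skin Layers in OCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for measuring epidermal thickness in optical coherence
    tomography (OCT) of skin with very few labels. Implements a multitask
    U-Net with a shared encoder, an object head (background/epidermis/scab)
    and an auxiliary contour head; a three-step transfer strategy that
    pretrains on an abundantly labelled source domain (thin, high-contrast
    rodent-like epidermis) and fine-tunes on a target domain (thick,
    low-contrast human-like epidermis) with one or three labelled B-scans
    per volume; fusion of object and contour probability maps into class
    masks; en-face epidermal thickness mapping per A-line; segmentation
    metrics (IoU, Dice, average symmetric surface distance, Hausdorff); and
    a speckle phantom generator with analytic ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
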
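Package: vesselseg
Title: Hybrid Classical/Deep-Learning Retinal Blood Vessel Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-phase pipeline for segmenting blood vessels in fundus
    photographs. Classical vessel enhancement (a matched-filter bank over
    orientations and widths, Hessian-eigenvalue multi-scale line detection,
    and a Gaussian scale-space stack) builds a per-pixel feature image that
    feeds a small U-Net with residual connections; the network's probability
    map is refined by morphological post-processing and thresholded into a
    binary vessel mask. Includes dataset readers for common fundus layouts
    (DRIVE, STARE, CHASE_DB1, HRF, flat), a seeded synthetic vascular-phantom
    generator with exact ground truth, a full segmentation-metrics suite
    (Jaccard, Dice/F1, precision, recall, accuracy, Cohen's kappa,
    specificity, AUC, FPS), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
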
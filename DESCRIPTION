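Package: scratchseg
Title: Segmentation and Quantification of In Vitro Scratch Wound Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated analysis pipeline for in vitro wound-healing
    (scratch assay) microscopy images. Provides a seeded synthetic
    scratch-assay generator with exact ground-truth masks, CLAHE
    preprocessing with area-based downscaling, quadrant tiling
    augmentation with an exact inverse merge, three encoder-decoder
    segmentation architectures (plain U-net, nested-skip U-net++ and
    attention-gated U-net) built on a seeded pure-R CNN engine with
    dice-loss training, and the full evaluation suite: wound-area
    quantification with signed percentage errors and pixelwise
    segmentation metrics (DSC, accuracy, IoU, precision, recall,
    specificity, ROC-AUC) under the wound-as-positive convention.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
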
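Package: cvseg
Title: Box-Seeded Chan-Vese Segmentation with Region-Proposal Utilities
    and Evaluation Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toolkit for bounding-box-seeded brain tumor segmentation on
    axial MRI-like images. Implements morphological Chan-Vese active
    contour segmentation initialized from a square level set inside a
    localization bounding box, the anchor generation, intersection-over-
    union labeling, box parameterization and loss mathematics of a Region
    Proposal Network, a full segmentation and classification evaluation
    suite (Dice, Rand index, variation of information, global consistency
    error, boundary displacement error, PSNR, MAE, Cohen's kappa,
    ROC/AUC), a Prewitt gradient-edge baseline, and a seeded synthetic
    phantom generator with Rician magnitude noise so the whole cascade is
    testable without external data or trained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
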
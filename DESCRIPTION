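Package: gtpick
Title: Transformer-Based Particle Detection for Cryo-EM Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Set-prediction particle picking for cryo-electron microscopy
    micrographs. Implements a DETR-family detector with reference-point
    cross-attention, group-wise one-to-many Hungarian label assignment, and a
    composite Focal + L1 + generalized-IoU objective, together with a
    synthetic low-SNR micrograph simulator, COCO/STAR/MRC interchange,
    training and inference loops, and precision/recall/F1 evaluation against
    ground-truth coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    jsonlite,
    png,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
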
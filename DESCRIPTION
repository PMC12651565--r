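Package: CTCscan
Title: Circulating Tumor Cell Detection from High-Resolution
    Immunofluorescence Slide Scans
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and enumeration of circulating tumor cells (CTC)
    in negatively enriched peripheral blood preparations imaged by
    multichannel fluorescence slide scanning. Provides nuclear
    segmentation of the DAPI channel (Otsu binarization, morphological
    closing, marker-controlled watershed), a trainable cell versus
    debris classifier over morphological features, background-corrected
    per-cell marker luminance quantification (EpCAM and cell-surface
    vimentin) on an 8-bit-equivalent scale, percentile threshold
    calibration from healthy-control cell populations, per-sample
    candidate-cell counting, and diagnostic evaluation with ROC curves,
    DeLong AUC comparisons and Youden-index cutoffs. A synthetic scan
    simulator with full ground truth supports validation of every stage
    without access to clinical material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    png,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
biocViews: CellBiology, Software, Classification, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
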
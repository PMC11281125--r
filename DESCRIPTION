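Package: fundustruct
Title: Structure-Aware Glaucoma Classification from Retinal Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale, fully tested re-implementation of a structure-aware
    glaucoma screening pipeline for retinal fundus photographs: background-aware
    preprocessing (threshold mask, mean-colour fill, CLAHE on the CIELab
    luminance channel), optic-disc extraction by a brightness-percentile mask
    and a circular Hough transform, patch-based retinal-vessel segmentation
    with a residual U-Net, and a three-branch convolutional classifier that
    fuses the preprocessed image with the two extracted structures through
    scaled dot-product attention (plus a concatenation-only ablation variant).
    Includes a seeded phantom-fundus generator with ground-truth vessel masks
    and disc geometry, ROC/AUC evaluation utilities, and an end-to-end
    pipeline runner. All networks run on a small built-in CPU engine, so the
    whole pipeline is reproducible from a seed with no external weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
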
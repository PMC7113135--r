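Package: wsidiag
Title: Region-of-Interest Detection, Tissue Segmentation and Diagnostic
    Classification for H&E Biopsy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for whole-slide hematoxylin and eosin
    (H&E) breast biopsy images. Detects diagnostically relevant regions of
    interest with a visual bag-of-words window classifier, converts color
    with CIELAB and Macenko stain deconvolution, segments regions into
    eight histopathologic tissue classes via SLIC superpixels and a
    trainable pixel classifier, and assigns one of four diagnoses (benign,
    atypia, ductal carcinoma in situ, invasive) from tissue frequency,
    co-occurrence and duct-centric layered structure features through a
    cascade of binary margin classifiers. Includes a deterministic
    synthetic-histology generator with pixel-level ground truth so every
    stage is trainable and testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    e1071,
    ranger,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
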
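Package: pdl1ic
Title: AI-Assisted PD-L1 (SP142) Immune-Cell Scoring for Breast Cancer IHC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based quantification of PD-L1 (SP142) immune-cell (IC)
    scores on immunohistochemistry image patches: HSV color-space
    thresholding of DAB-stained pixels, morphological denoising, exclusion
    of tumor epithelium and necrosis via a trainable pixelwise segmenter or
    oracle masks, gap-filling iterative dilation, and the IC area ratio with
    2- and 4-category binning. Also implements the multi-rater concordance
    statistics used in ring studies of IC scoring - ICC(3,1), ICC(2,1),
    Fleiss' kappa with interpretation bands, accuracy/AUC/weighted-F1, and
    AI-acceptance analysis - together with synthetic IHC-patch and
    synthetic-rater generators so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
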
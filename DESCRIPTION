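Package: thinseg
Title: Segmentation and Imbalance-Aware Evaluation of Thin Radiopaque
    Structures in X-ray Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for segmenting transcatheter heart valve (THV)
    bioprostheses — thin, reticular radiopaque structures — in X-ray
    angiographic frames, and for evaluating such segmentations under
    extreme class imbalance.  Provides a synthetic angiographic phantom
    generator with paired gold-standard masks, a small U-Net encoder—
    decoder trained with binary cross-entropy or alpha-balanced focal
    loss, three probability-map binarization schemes (fixed threshold,
    Otsu, top-k "prior knowledge of foreground pixels"), the
    imbalance-aware distance metrics D1 and D2 alongside conventional
    pixel metrics, and an experiment layer that runs the hyperparameter
    tuning grid, the closest-to-origin model selection and frame-type
    stratified evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
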
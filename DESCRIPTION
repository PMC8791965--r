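Package: fetalage
Title: Attention-Guided Dual-Branch Convolutional Regression of Gestational Age
    from Fetal Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts gestational age (in days) from multi-plane stacks of
    T2-weighted-like fetal brain image slices using a dual-branch
    convolutional regression network. A global branch regresses age from the
    whole image; a soft attention heatmap (channel-maximum of absolute
    last-layer activations, truncated-ReLU normalized and re-weighted by a
    centered 2D Gaussian) masks the input for a local branch, and branch and
    plane predictions are averaged. Includes a synthetic multi-plane phantom
    generator with known age labels and truth masks, a preprocessing and
    dataset-splitting pipeline, a small-scale trainable backbone with full
    backpropagation (Rcpp kernels), an external-site fine-tuning protocol,
    and the evaluation suite: R-squared, mean absolute error, Lin's
    concordance correlation coefficient with confidence interval and McBride
    agreement class, and quantile Bland-Altman agreement curves.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), tidyr, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
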
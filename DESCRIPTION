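Package: bmseval
Title: Evaluation Toolkit for Brain Metastasis Segmentation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative machinery for evaluating automated and human
    segmentation of brain metastases on 3D imaging: volumetric
    overlap and surface metrics (Dice similarity coefficient, relative
    volume difference, average surface distance), per-lesion analysis
    (connected-component labelling, axial diameter, ground-truth to
    prediction matching), nonparametric statistics with percentile
    bootstrap confidence intervals, a randomized-crossover multi-reader
    multi-case comparison pipeline, a synthetic lesion phantom generator
    for end-to-end testing without imaging data, and an architecture
    calculus that counts parameters of V-Net-style encoder-decoder
    networks before and after bottleneck compression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    RANN,
    matrixStats,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
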
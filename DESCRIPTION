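Package: ttcseg
Title: Deep-Learning Segmentation and Infarct-Size Quantification for
    TTC-Stained Heart Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying myocardial infarct size (IS) from digital
    photographs of triphenyl tetrazolium chloride (TTC)-stained heart slices.
    Provides a synthetic phantom generator that emulates ischemia/reperfusion
    cohorts with known ground truth, image preprocessing (background removal,
    aspect-ratio padding, uniform resizing with SSIM/PSNR quality control), a
    five-class encoder-decoder (U-Net) semantic segmentation network trained
    with a composite loss of weighted cross-entropy, mean absolute error and
    Dice similarity, mass-normalized infarct-size planimetry, and a full
    evaluation suite: Dice, accuracy, boundary-F1 and average-precision
    segmentation metrics plus Pearson/linear-regression, Bland-Altman,
    ANCOVA-versus-identity and Kolmogorov-Smirnov agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    EBImage,
    png,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
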
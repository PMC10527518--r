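Package: radsig
Title: Radiomic Signature Development for Small Renal Masses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to develop and evaluate a CT radiomic signature that
    discriminates benign from malignant small renal masses. Implements the
    full signature-development pipeline: redundant-feature elimination,
    z-score standardization with train-to-unseen transfer, random walk
    oversampling of the minority class, an ordered acquisition-parameter
    reproducibility chain (Kruskal-Wallis and Spearman screening against
    scanner model, convolution kernel, pixel spacing, slice thickness and
    tube voltage), Monte Carlo cross-validated Mann-Whitney feature scoring
    with top-K signature selection, and a k-nearest-neighbour classifier in
    PCA or ICA component space with MCCV-based hyperparameter tuning. A
    synthetic cohort generator with planted redundancy, scanner batch
    effects and class-informative features makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
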
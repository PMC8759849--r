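Package: ktafs
Title: Kernel-Target Alignment Feature Selection and Convolutional
    Classification for Gene Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection and multi-class classification for
    high-dimensional gene expression matrices. Implements an unsupervised
    latent kernel-target alignment selector (per-gene Gaussian kernels
    aligned to a latent-space target kernel via sparse non-negative
    weights), classical filter selectors (information gain, mRMR with MID
    and MIQ criteria, Relief-F/Relief-D, CFS), an artificial-bee-colony
    wrapper, a one-dimensional convolutional softmax classifier with
    repeated stratified k-fold cross-validation, confusion-matrix and
    classification-report utilities, and a synthetic data generator with
    planted informative genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
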
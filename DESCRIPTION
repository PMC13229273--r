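Package: phonorsa
Title: Representational Similarity Analysis of Cross-Modal Speech Phonology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end representational similarity analysis (RSA) pipeline
    for testing whether visual speech evokes phonological representations that
    are shared with other language forms (auditory speech, or dynamic text),
    and whether the strength of that cross-modal alignment tracks reading
    ability. Implements constrained trial-sequence generation for a sparse
    sampling fMRI paradigm, theoretical dissimilarity models over a factorial
    word set, synthetic BOLD simulation with planted representational geometry,
    first-level GLM estimation with discrete-cosine high-pass filtering and
    AR(1) prewhitening, cross-validated Mahalanobis (crossnobis) distances with
    multivariate noise normalization, volumetric searchlight mapping with
    cluster-level permutation and FDR control, and a conditional two-step
    model-testing procedure with Kendall tau-a model comparison, effect sizes,
    brain-behaviour correlation, and multidimensional scaling visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
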
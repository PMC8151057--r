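Package: choosyn
Title: Selecting the Number of Muscle Synergies from Surface EMG of Cyclic
    Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts muscle synergies from multi-channel surface
    electromyographic (sEMG) recordings of cyclic locomotion and selects the
    number of synergies. Implements the full pipeline: gait-cycle
    segmentation and time normalization, Butterworth envelope extraction,
    amplitude normalization, 10-cycle subgroup factorization by non-negative
    matrix factorization with alternating non-negative least squares
    (NMF/ANLS), cosine k-means sorting of synergies across subgroups, the
    ChoOSyn model-order criterion built on synergy consistency and
    intra-level similarity, and three variance-accounted-for (VAF) baselines
    (threshold, elbow, plateau). Includes a pseudo-real sEMG simulator with
    known ground truth and a benchmark harness scoring every criterion by
    fraction correct, mean error, and root-mean-square error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
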
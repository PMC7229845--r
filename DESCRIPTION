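Package: tempoalign
Title: Temporal Alignment and Differential Progression Scoring for
    Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Aligns pairs of gene expression time courses of different
    length and sampling density with dynamic time warping, post-processes
    the alignment by truncating spurious start and end matches, and jointly
    assesses temporal similarity with four metrics: per-series percentage
    of alignment, Spearman correlation of aligned values, and a permutation
    p-value under a Gaussian approximation of the shuffle null. Gene pairs
    with similar temporal patterns (STP) are scored for differential
    progression with a piecewise-regression-based Progression Advance
    Score (PAS), a condition-level c-PAS, and an adjusted PAS. Includes
    median-of-ratios normalisation, fold-change filtering and unit scaling
    for raw expression matrices, and a simulator for time-shift,
    speed-change, mixed-regime and dissimilar trajectory pairs with
    controlled Gaussian noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
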
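Package: grndiff
Title: Differential Analysis of Binary Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical framework for detecting group-level differences
    between two sets of samples described by sparse binary regulatory
    matrices, such as transcription-factor target activation networks
    inferred from single-cell data. Provides three global permutation
    tests (a Hamming-kernel U-statistic dissimilarity ratio, a
    Jaccard-distance pseudo-F test, and a PCA-based separation score),
    two feature-level tests (per-feature Mann-Whitney with Fisher
    combination, and an aggregated Fisher exact test), a five-scenario
    binary-matrix simulator with a power benchmark, and downstream
    utilities for per-TF testing, effect sizes, category classification
    and differential-activation ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
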
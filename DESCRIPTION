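Package: netpage
Title: Network Propagation-Based Association Testing of Rare Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-based association testing for rare variants via network
    propagation. Signed rare-variant burden matrices are smoothed over a
    weighted tissue-specific gene-interaction network by an iterative
    diffusion operator, and the smoothed gene scores are related to a binary
    phenotype through L1-penalized logistic regression with stability
    selection. Includes network loading, binarization and degree-preserving
    randomization, variant filtering and burden construction with
    odds-ratio-based effect orientation, a closed-form propagation oracle,
    downstream model comparison and enrichment utilities, and a simulation
    framework with planted neighbourhood mutation frequencies for power and
    calibration analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    VariantAnnotation,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
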
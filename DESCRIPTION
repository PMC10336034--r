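Package: bustedmh
Title: Episodic Diversifying Selection Tests with Synonymous Rate Variation
    and Multinucleotide Substitutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood branch-site codon models for detecting
    episodic diversifying selection (the BUSTED random-effects framework)
    extended with site-to-site synonymous rate variation (+S) and
    instantaneous double- and triple-nucleotide substitutions within a codon
    (+MH).  Provides the full model hierarchy (BUSTED, +S, +MH, +S+MH and the
    intermediate +S+2H), likelihood-ratio tests for selection with the
    50:50 chi-squared boundary mixture null, AICc-based Akaike weights and
    model-averaged p-values, branch-site empirical Bayes diagnostics, an
    event-logging sequence simulator, and false-positive/power grid harnesses.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    phangorn,
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
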
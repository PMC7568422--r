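Package: ebpat
Title: Empirical-Bayes Expression-Pattern Posteriors for Multi-Condition
    RNA-seq Candidate Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a negative-binomial empirical-Bayes model with a beta
    prior on the negative-binomial probability parameter to gene-level
    RNA-seq counts observed under several conditions, and computes for
    every gene the posterior probability of each multi-condition equality
    pattern (which condition means are equal, which differ).  Provides
    posterior-probability-based false discovery rate control, an
    order-restriction gate that filters genes whose normalized condition
    means follow a phenotype-derived ranking, a mechanical annotation
    filter for secreted-factor candidates, median-of-ratios library-size
    normalization, and a fully seeded synthetic count and phenotype
    generator so the whole screen is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
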
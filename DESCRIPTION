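Package: spliceKey
Title: Key Splicing-Factor Discovery from Splicing and Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differential alternative splicing from exon and
    exon-exon junction counts with a Dirichlet-multinomial likelihood-ratio
    test over splice-graph events, builds signed splicing and expression
    signatures from perturbation experiments, compares a disease signature
    against a compendium of splicing-factor perturbation signatures with
    Fisher's exact test under a noncentral (log-odds-ratio) null, and
    normalizes differential-event counts across heterogeneous experimental
    designs with covariate linear models. Ships a synthetic-data generator
    with planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
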
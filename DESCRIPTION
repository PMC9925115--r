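Package: pkanet
Title: Kinome Network Propagation and Screen Statistics for PKA-Driven Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates kinase activity and abundance profiles from two
    proteomic platforms across engineered cell lines carrying activating or
    inhibiting PKA constructs, propagates the harmonized scores over a gene
    functional-interaction network by random walk with restart, combines
    propagated heats across cell lines, calls significant PKA-adjacent
    kinases by permutation, and extracts the focus-gene subnetwork. Also
    implements the accompanying high-throughput screening statistics
    (within-plate z-scores, log2 fold change versus plate median with
    Student's t-tests, growth-curve AUC, four-parameter logistic EC50 fits,
    and log-linear protein half-life fits) and a synthetic-data generator
    that emulates the full study design for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
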
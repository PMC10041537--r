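Package: duplexspectra
Title: Duplex-Consensus Mutational Spectra from Reporter-Region Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of duplex (double-strand consensus)
    sequencing of a reporter target region: tag parsing and family grouping,
    single-strand and double-strand consensus calling with end trimming,
    ungapped placement and pileup-based substitution calling, unique-mutation
    collapse, 96-channel trinucleotide mutational spectra with target-composition
    normalization and background subtraction, cosine-similarity comparison
    against substitution signatures, probability-logo (binomial log-odds)
    sequence-context enrichment with Bonferroni thresholds, and exact
    Mann-Whitney statistics for transgenic reporter mutant-frequency assays.
    Includes a seeded synthetic duplex-read generator so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
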
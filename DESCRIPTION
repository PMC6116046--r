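Package: neosexr
Title: Gametolog Phasing, Divergence and Dosage-Compensation Analysis for
    Avian Neo-Sex Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study the degeneration of young (neo-) sex chromosomes
    from sex-labelled resequencing and expression data. Phases Z and W
    gametolog sequences from diploid genotype calls of males (ZZ) and
    females (ZW) using sex-specific variant patterns, detects loss of the W
    copy from normalized DNA coverage, quantifies functional (dN) and silent
    (dS) divergence between gametologs and against an outgroup with a
    counting (NG86-style) estimator, measures GC erosion of the
    non-recombining W, and tests whether female-to-male expression ratios
    decline with W degeneration. Ships a codon-level gametolog-evolution
    simulator with recorded ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
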
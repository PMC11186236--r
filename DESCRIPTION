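Package: omicsMR
Title: Multi-Omics Mendelian Randomization for Drug-Target Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-sample Mendelian randomization with cis-acting molecular
    quantitative trait loci as instruments, for triangulating drug targets
    against a disease outcome. Implements summary-statistics input and allele
    harmonization, LD clumping and instrument-strength/Steiger filtering,
    Wald-ratio/IVW/MR-Egger estimators with Cochran's Q, summary-data-based MR
    (SMR) with the HEIDI linkage test, Bayesian colocalization via approximate
    Bayes factors, fixed-effect meta-analysis across sources, FDR gating,
    replication counting over an outcome panel, three-tier evidence
    classification, and a seeded multivariate-normal simulator of regional
    GWAS summary statistics under LD so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
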
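Package: phenobench
Title: Simulation Benchmark for Phenocopy Effects on Genetic Association Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates case-control and nuclear-family genotype data under a
    main-effect logistic disease model and a purely epistatic three-locus
    penetrance model on a synthetic chromosome with block linkage
    disequilibrium, injects phenocopies at graded levels by two mechanisms
    (control relabelling and alternative-determinant substitution), and
    quantifies how single-point association, the transmission disequilibrium
    test, logistic interaction regression and multifactor dimensionality
    reduction degrade as the phenocopy fraction rises.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
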
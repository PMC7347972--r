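Package: plastocomp
Title: Comparative Plastid Genome Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated plastid (chloroplast)
    genomes: detection of the quadripartite LSC/SSC/IR structure and IR junction
    gene context, ndh-gene intactness auditing, codon usage and RSCU, dispersed
    repeat and microsatellite (SSR) discovery with cross-species polymorphism
    calling, hypervariable-marker ranking from multi-genome alignments via a
    sequence-variability statistic, and site-level positive-selection scanning
    under M0/M8a/M8 codon models with likelihood-ratio tests and empirical-Bayes
    site posteriors. Includes a synthetic plastome evolver that emits genomes,
    the true alignment, and a machine-readable truth log so every stage can be
    validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
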
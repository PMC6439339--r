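Package: pharmapop
Title: Population Pharmacogenomics of Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies between-population variation of pharmacogenomic
    SNPs and turns it into population-level testing priorities.
    Implements minor allele frequency and Wright's fixation index from
    per-population allele frequencies, linkage-disequilibrium pruning,
    identity-by-state distances with classical multidimensional scaling,
    supervised ancestry estimation against a reference panel via a
    binomial-likelihood EM on the simplex, ancestry-genotype linear
    regression, a composite Euclidean statistic ranking effect-allele
    divergence between two populations, and confusion-matrix scoring of
    genotyping assays against sequencing-derived calls. A
    synthetic-cohort generator (Balding-Nichols reference panel,
    Dirichlet admixture) makes every stage testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
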
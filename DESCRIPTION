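Package: taintQTL
Title: Cis/Trans eQTL Mapping and Candidate Marker Selection for Boar Taint
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A systems-genomics pipeline from SNP genotypes and two-tissue
    RNA-Seq count matrices to candidate markers for selection against boar
    taint in pigs. Implements variant quality control (call rate, exact
    Hardy-Weinberg test, minor allele frequency, sliding-window linkage
    disequilibrium pruning), count filtering and log-CPM normalisation with a
    mean-variance precision-weight trend, a matrix-formulated cis/trans eQTL
    scan with Benjamini-Hochberg false discovery rate control, an
    empirical-Bayes hierarchical mixture model over tissue-activity
    configurations fitted by expectation-maximisation, breeding-value and
    expression association filtering of eQTLs, chromosomal density and
    co-expression statistics, a binomial trait-QTL interval enrichment test,
    and selection of candidate eQTL genotypes carried by low-breeding-value
    animals. Ships a synthetic-data generator emulating the assumed study
    design (48 animals in three breeding-value groups, linked genotypes,
    negative-binomial counts with planted cis effects, and a mock trait-QTL
    interval database) so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    IRanges,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
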
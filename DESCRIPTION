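Package: netkda
Title: Bayesian Network Construction and Key Driver Analysis for Gene
    Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds consensus Bayesian gene-regulatory networks from
    discretized expression matrices with correlation and eQTL priors,
    checks their scale-free and small-world topology, and identifies
    "key driver" genes by downstream-count z-scores (type 1) and by
    enrichment of GWAS candidate genes in downstream neighborhoods
    (type 2). Includes cross-cohort replication with permutation nulls
    for key-driver overlap, a synthetic-data generator (ground-truth
    DAGs with hub regulators plus linear-Gaussian expression) for
    end-to-end validation, and closed-form cellular assay metrics
    (doubling time, Seahorse-derived mitochondrial phenotypes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
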
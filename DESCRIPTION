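Package: driverscape
Title: Consensus Prioritization of Somatic Driver Mutations, Genes and Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes oncogenic driver events in somatic mutation cohorts.
    From an annotated MAF-format cohort carrying per-mutation pathogenicity
    scores, driverscape calls recurrent high-score driver mutations and
    loss-of-function "extreme" mutations, combines per-gene significance from
    two mutation-recurrence methods with Fisher's method and
    Benjamini-Hochberg correction, ranks genes by a weighted Borda consensus
    over known driver catalogs, assigns five-tier pathogenicity levels,
    computes Gaussian-model driverness scores from false discovery rates,
    tests driver pathways by hypergeometric enrichment, detects mutually
    exclusive and co-occurring driver gene pairs with Fisher's exact test,
    and annotates druggability from drug-gene interaction tables. A
    synthetic-cohort generator with planted driver signal makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
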
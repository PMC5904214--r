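Package: p52signet
Title: Gene-Signature Derivation, Survival Stratification, and
    Interaction-Network Analysis for Non-Canonical NF-kB Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for deriving a transcriptional signature of
    non-canonical NF-kB (p52) activity from a two-factor expression
    experiment and carrying it through to human-cohort validation: paired
    tumor/normal differential expression with Benjamini-Hochberg control,
    hypergeometric and Fisher over-representation statistics, sum- and
    vote-based patient stratification with Kaplan-Meier / log-rank survival
    analysis truncated to five years, Steiner-minimal-tree extraction of
    mediator subnetworks from protein-interaction graphs, and hierarchical
    clustering of cohorts on signature genes.  Seeded synthetic-data
    generators emulate each required input (factorial microarray, matched
    tumor/normal pairs, survival cohort, scale-free interactome), so every
    stage is testable without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
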
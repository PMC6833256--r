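Package: coregtopo
Title: Topology Consistency of TF-miRNA Co-Regulatory Networks Across
    Differential-Expression Methods
Version: 0.1.0
Authors@R:
    person("coregtopo", "developers", email = "coregtopo@example.org",
           role = c("aut", "cre"))
Description: Builds disease-specific transcription-factor / microRNA
    co-regulatory networks from sets of differentially expressed genes and
    quantifies how consistent their key players (hub-degree nodes, minimum
    dominating set, minimum connected dominating set) are across four
    simplified count-based differential-expression procedures (a DESeq-like
    and an edgeR-like negative-binomial exact test, and variance-stabilised
    and voom-style log-cpm pipelines followed by a moderated t-test).
    Includes a seeded synthetic-data generator (overdispersed negative
    binomial counts with planted fold changes, a scale-free-ish typed
    interaction database, a disease annotation enriched around planted
    regulators), hypergeometric recovery of co-regulating miRNAs, an exact
    branch-and-bound minimum dominating set solver, a deterministic greedy
    minimum connected dominating set heuristic, overlap-coefficient
    consistency tables, and a random-gene-set robustness test with
    empirical p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
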
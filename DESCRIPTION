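Package: replicell
Title: Multilevel Selection in Protocell Populations of Catalytic Replicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based simulator of protocells that each contain a
    population of replicating catalytic molecules of two types (P and Q)
    competing for a conserved substrate. Each replicator carries eight
    heritable catalytic activities; serving as a catalyst sequesters a
    molecule so that it cannot simultaneously serve as a template, creating
    a conflict between molecular-level selection (within protocells) and
    cellular-level selection (between protocells). The package reproduces
    the spontaneous catalytic, informatic and numerical symmetry breaking
    by which the two molecular types differentiate into non-catalytic
    genomes and catalytic enzymes, and ships the accompanying analytical
    machinery: two-level ancestor tracking, Price-equation decomposition of
    trait change, within/between-cell variance partition and relatedness,
    Fisher reproductive values, end-state phase classification, and a
    deterministic phase-plane model of the mean catalytic activities with
    equilibria, basins of attraction and an inclusive-fitness potential.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
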
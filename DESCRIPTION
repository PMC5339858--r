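Package: cernanoise
Title: Stochastic Modelling of miRNA-Mediated ceRNA Crosstalk and Protein
    Expression Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how competition of transcripts for a shared
    microRNA (the ceRNA effect) shapes protein expression noise and the
    correlations of interacting proteins. Implements the mass-action
    reaction network of one miRNA, two ceRNAs, their miRNA-bound
    complexes, two proteins and a binary protein complex; an exact
    Gillespie stochastic simulator with stationary-moment estimation;
    deterministic steady states and second moments via the Linear Noise
    Approximation (Lyapunov equation); derepression-size and
    channel-capacity analyses under the Small Noise Approximation; and a
    config-driven scenario runner reproducing the canonical circuit
    comparisons (miRNA-only vs ceRNA regulation, miRNA recycling, Pearson
    sign reversal of interacting proteins, complex-level capacity maps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
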
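Package: coevotrait
Title: Correlated Evolution of ENaC Proteolytic Cleavage Sites and PY Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how protease cleavage sites and PY motifs in
    epithelial sodium channel (ENaC) subunits evolved across vertebrates.
    Detects polybasic furin/prostasin cleavage tracts and C-terminal PY motifs
    in aligned protein sequences and emits binary trait matrices; fits
    continuous-time Markov models of correlated binary-trait evolution
    (independent and dependent Pagel-style models, and habitat-conditioned
    variants) on a fixed phylogeny by Felsenstein pruning; compares nested
    models with likelihood-ratio tests; and reconstructs ancestral states by
    Markov chain Monte Carlo with node fossilization, stepping-stone marginal
    likelihoods and log Bayes factors. Includes a synthetic-data module
    (birth-death trees, exact trait simulation, motif-implanted alignment
    fixtures) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
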
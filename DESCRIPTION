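Package: cgpic
Title: Coarse-Grained Modeling of Promoter DNA Opening in Pol II Pre-Initiation Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based (Go-type) coarse-grained molecular dynamics and
    trajectory analysis for protein-DNA complexes, built around the promoter
    melting problem in the RNA polymerase II pre-initiation complex. Provides a
    three-sites-per-nucleotide DNA model with orientation-dependent base
    pairing, a C-alpha protein model with native-contact potentials, calibrated
    protein-DNA contact wells, Debye-Hueckel electrostatics, Langevin dynamics
    with annealing and sequence-mismatch protocols, and bespoke trajectory
    statistics: DNA bubble size, state-specific contact fractions, discrete
    state assignment, and fork-loop gate distances. Includes a synthetic-data
    generator (ideal B-DNA, toy clamp/promoter systems with prescribed
    contact-set structure) so the full pipeline is testable without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
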
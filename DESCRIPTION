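Package: crisscut
Title: Stochastic Simulation of Crisscross DNA Ribbon Scission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds rule-based site-graph models of crisscross DNA ribbons
    carrying a cut interface, toehold extensions and wobble-weakened binding
    sites, and simulates their scission by joint toehold-mediated strand
    displacement with an exact continuous-time Monte Carlo (Gillespie)
    engine subject to a graph-locality ("three-point") constraint.
    Includes scission detection and ensemble summaries, parameter sweeps
    over slat length, extension length and wobble layout, export of the
    generated models as Kappa (KaSim 4 dialect) rule files, and a coarse
    growth-and-cut branching model of exponential ribbon amplification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
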
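Package: g1sbn
Title: Boolean Network Analysis of the lncRNA-miR-34a Axis at the G1/S
    Checkpoint in Non-Small Cell Lung Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Logical (Boolean) modelling toolkit for gene regulatory
    networks under fully asynchronous updating, built around a 32-node
    model of the DNA-damage-activated G1/S checkpoint in non-small cell
    lung cancer in which the long non-coding RNAs ANRIL and UFC1 act as
    sponges for the tumour suppressor microRNA miR-34a.  Provides rule
    parsing and validation for a BoolNet-style text format, complete
    fixed-point enumeration by constraint propagation, reachable
    state-transition-graph construction, attractor detection via terminal
    strongly connected components, Monte Carlo and exact (linear-solve)
    phenotype absorption probabilities, signed feedback-circuit
    enumeration with discrete-Jacobian functionality analysis, in silico
    knockout/over-expression screens, and a seeded random-network
    generator with brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    Matrix,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
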
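Package: hybridkin
Title: Coarse-Grained Simulation of DNA Oligomer Hybridization Kinetics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A rigid-nucleotide coarse-grained model of DNA with Langevin and
    Brownian rigid-body dynamics, cluster-move Monte Carlo with umbrella
    sampling, and direct forward flux sampling for rare-event rate
    estimation. The package builds duplex, misaligned-register and
    pseudoknot configurations for arbitrary oligomer sequences, detects
    base pairs and secondary-structure registers from microstates,
    classifies hybridization pathways (zippering, inchworm and pseudoknot
    internal displacement, detachment), computes free-energy profiles over
    base-pair number, apparent activation enthalpies from rate-temperature
    series, and sequence-relative association rates in both a
    sequence-averaged and a sequence-dependent parameterization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
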
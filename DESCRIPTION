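Package: avidula
Title: Desk-Scale Digital Evolution of Self-Replicating Programs with
    Metabolic Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An agent-based digital-evolution laboratory in the Avida
    tradition: populations of self-replicating 120-instruction programs
    evolve on a small toroidal lattice under configurable mutation rate,
    chemostat resource abundance, and carrying capacity.  Organisms earn
    merit (execution speed) by computing bitwise logic tasks on 5-bit
    environmental inputs and can exchange register values with their
    eight lattice neighbors, which permits the emergence of metabolic
    signaling.  The package bundles the assays needed to analyze such
    runs: a population fitness assay, isolation merit and gestation
    measurement, viability scoring, phenotype profiling, marginal
    utility of a named process via nop-X knockouts, copy-loop
    localization and transplantation, per-site genotypic and phenotypic
    Shannon heterogeneity, kernel-density fitness-peak isolation,
    Hartigan dip unimodality testing, and signaling-positive population
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
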
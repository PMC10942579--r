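Package: angiopattern
Title: Order-Disorder Analysis of Tip-Stalk Patterning in Angiogenesis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multicellular VEGF/NOTCH lateral-inhibition modeling and spatial
    statistics for angiogenic Tip-Stalk cell patterning. Integrates a
    five-species (NOTCH, Delta, Jagged, NICD, VEGFR) ordinary differential
    equation system with shifted-Hill regulation on periodic hexagonal
    lattices to steady state, classifies Tip cells from bimodal Delta
    distributions, and quantifies order-disorder pattern statistics: Tip
    fraction, disorder index, pseudopotential landscapes, dose-response
    transition fits, and shielded hop-distance Tip-Tip spacing distributions
    on arbitrary cell-adjacency graphs. Includes three phenomenological
    sprout-selection models (cell-autonomous, repulsion, random-uniform
    maximal dispersion), absorbing-state fate-transition tracking for
    mini-sprout/sprout dynamics, neighborhood fibronectin intensity
    statistics, and synthetic-data generators with known ground truth for
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    igraph,
    Matrix,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
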
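Package: alewifesim
Title: Individual-Based Eco-Evolutionary Simulation of Alewife Morphology in a Size-Structured Prey Community
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates rapid evolution of body size and gill-raker count in a
    landlocked planktivorous fish (alewife, Alosa pseudoharengus) foraging on a
    size-structured zooplankton community. Fish are modelled individually with
    diploid biallelic quantitative trait loci for growth and gill-raker count,
    stochastic von Bertalanffy growth, Beverton-Holt prey-mediated survival and
    promiscuous annual mating. Prey are modelled as two or three allometrically
    scaled size clusters, each with 21 genotype-determined body-size classes,
    updated by discrete Lotka-Volterra difference equations. Includes scenario
    grids for sensitivity analyses, a fixture generator for fast test
    configurations, a command-line interface and tidy CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
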
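Package: bdchrono
Title: Birth-Death Chronospecies Models for Fossil and Phylogenetic Diversification Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference under the birth-death chronospecies (BDC)
    process, in which new (morpho)species arise by budding or bifurcating
    cladogenesis and by anagenetic replacement. Provides a general-sampling-
    algorithm simulator of complete birth-death trees conditioned on the number
    of extant tips (constant or piecewise-constant rates), mapping of
    chronospecies and stratigraphic ranges onto simulated trees, degradation of
    ranges into incomplete and fossil-occurrence data, exact likelihoods for
    extant-timetree and stratigraphic-range data (with skyline variants),
    maximum-likelihood fitting and likelihood-ratio testing of the equal,
    compatible and incompatible rates models, Bayesian Markov chain Monte Carlo
    samplers with posterior model checks, and statistics summarising the
    prevalent mode of speciation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
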
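Package: breedopt
Title: Budget-Constrained Breeding-Scheme Simulation and Bayesian Optimisation
Version: 0.1.0
Authors@R:
    person("breedopt", "developers", email = "breedopt@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of genomic-selection breeding campaigns
    under explicit resource constraints (total budget, phenotyping and
    genotyping costs, number of selection cycles), and optimisation of the
    scheme's decision variables (selection intensities, budget split,
    phenotyping period) with a Gaussian-process surrogate, expected
    improvement, constant-liar batching and focus search.  Includes a
    synthetic founder generator emulating a homozygous soybean-like panel,
    Poisson crossover meiosis on a Morgan-scale genetic map, ridge (RR-BLUP
    style) genomic prediction, TSP-based mating design, and a random-search
    baseline with paired evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
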
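Package: beehab
Title: Phylogenetic Comparative Analysis of Bee Brain Size and Habitat Occupancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking relative brain size to habitat occupancy in bees
    (and other species-level comparative datasets). Implements phylogenetic
    generalized least squares of log brain mass on log body size with Pagel's
    lambda estimated by maximum likelihood, relative brain size as the model
    residuals, a fixed-margin (Patefield) randomization null model scoring the
    degree of occupancy of natural, agricultural and urban habitats from
    georeferenced occurrence records, phylogenetic signal estimation with a
    likelihood-ratio test, and a phylogenetic Bernoulli (logistic) regression of
    high versus low occupancy on relative brain size with the phylogenetic
    covariance as a random effect, fitted by Laplace-approximated maximum
    likelihood. A synthetic-data generator produces birth-death phylogenies,
    Brownian-motion allometric traits and habitat-labelled occurrence records so
    the whole pipeline can be exercised end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
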
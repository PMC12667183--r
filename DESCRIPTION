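Package: soilq
Title: Soil Quality and Microbial Driver Analysis for Manure-Substitution
    Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for fertilizer-substitution field trials in
    which part of the chemical nitrogen is replaced by organic manure.
    Implements the radar-area soil quality index with direction-aware
    linear (min-max) indicator scoring, ecoenzymatic stoichiometry vector
    length and angle from the six standard C/N/P-acquiring hydrolases,
    one-way and two-way ANOVA including exact reconstruction from
    published means and standard deviations, Tukey-based compact letter
    displays, phylum-level community summaries (relative abundance,
    Gini-Simpson diversity, Bray-Curtis dissimilarity, PERMANOVA), Mantel
    permutation tests, and response-permutation significance for random
    forest feature importance. A configurable synthetic-data generator
    reproduces the randomized complete block structure of a five-rate
    manure-substitution trial so every stage can be exercised end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
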
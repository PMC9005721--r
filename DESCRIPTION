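Package: spatSDM
Title: Bias-Aware Species Distribution Modelling with Spatial Thinning and
    Block Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A presence-only species distribution modelling pipeline for
    citizen-science occurrence data with strong spatial sampling bias.
    Provides ESRI ASCII grid input/output and covariate extraction, spatial
    thinning of occurrence records at a minimum nearest-neighbour distance,
    combined disk + latitude-filtered pseudo-absence generation, two-stage
    covariate selection (Pearson correlation grouping plus random-forest
    Gini and permutation importance), spatially blocked k-fold
    cross-validation of random-forest classifiers, and habitat-suitability
    map projection under present and substituted future climate stacks.
    Includes a synthetic-world generator with a known logistic suitability
    surface and accessibility-biased sampling so every stage is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    pROC,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
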
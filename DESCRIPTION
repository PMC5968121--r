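Package: nichecast
Title: Presence-Only Niche Modelling and Land-Cover Scenario Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for presence-only habitat-suitability analysis of plant
    invasions: maximum-entropy (L1-regularised log-linear) niche models with
    AICc-based tuning over feature classes and regularisation multipliers,
    multi-metric evaluation (rank AUC, Continuous Boyce Index, jackknife
    variable importance, percent contribution), ten-percentile threshold
    binarisation, Markov-chain land-cover projection with multi-layer
    perceptron transition potentials, and scenario-wise range-change
    accounting. Includes a synthetic-landscape generator with known
    log-linear truth so the whole pipeline can be exercised end-to-end
    against ground truth, plus ESRI ASCII Grid raster I/O and a
    configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    nnet,
    yaml,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'evaluation.R'
    'features.R'
    'landcover.R'
    'maxent-fit.R'
    'maxent-predict.R'
    'nichecast-package.R'
    'occurrences.R'
    'pipeline.R'
    'raster.R'
    'scenario.R'
    'selection.R'
    'synthetic.R'
    'utils.R'
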
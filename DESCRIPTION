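Package: bambooclim
Title: Bioclimatic Niche Modelling and Warming-Level Projection of
    Invasive Bamboo
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for presence/absence bioclimatic envelope modelling of
    invasive bamboo (Phyllostachys edulis and P. bambusoides) at weather
    stations, and for projecting potential habitat under pattern-scaled
    warming scenarios. Computes Kira's warmth and coldness indices and
    seasonal precipitation splits from monthly station climatologies; fits
    and selects binomial-logit niche models by all-subsets AICc search
    with collinearity screening; validates them by leave-one-out
    cross-validation with Youden-threshold classification and
    imbalance-aware metrics (AUC, MCC, informedness); builds climate
    scenarios at 1.5-4.0 degC global warming levels from scaling patterns
    and a global anomaly series with a preindustrial offset; and maps
    thresholded habitat probability onto climate grids with habitat-area
    fractions, northern-limit shifts, and MESS extrapolation diagnostics.
    A synthetic-world generator with known ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
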
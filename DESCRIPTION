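Package: eflowalt
Title: Hydrologic Alteration and Fish Biodiversity Loss for Stream Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies hydrologic (streamflow) alteration at stream gauges
    from daily discharge records, extrapolates alteration to ungauged stream
    reaches with disturbance-covariate random-forest models, and converts
    alteration into probabilities of native-fish biodiversity loss via
    quantile-regression tipping points with compounded-uncertainty bounds.
    Includes a synthetic gauge-network generator that emulates reference and
    disturbance-perturbed daily flow regimes, disturbance-linked covariates,
    and wedge-shaped fish-richness responses with a known tipping point, so
    the full pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    quantreg,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
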
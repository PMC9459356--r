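Package: drsurv
Title: Dynamic and Relative Survival Models for Hazard Extrapolation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits and extrapolates survival models for health technology
    assessment, with an emphasis on additive relative-survival (excess
    hazard) models that bound the modelled hazard below by general-population
    mortality. Implements dynamic survival models and dynamic relative
    survival models (state-space models on the log hazard or log excess
    hazard with local-level, local-trend and damped-trend evolutions),
    parametric and restricted-cubic-spline excess-hazard models including a
    flexible cure model, life-table handling with a uniform-deaths background
    hazard, a simulation-study engine reporting bias and mean squared error
    of the log hazard, and a three-state partitioned-survival
    cost-effectiveness model with probabilistic sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rjags,
    flexsurv,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
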
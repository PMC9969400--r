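Package: felscreen
Title: Umbrella-Sampling Free-Energy Landscapes and Reaction-Barrier
    Screening for Enzymatic Ester Hydrolysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs free-energy profiles and landscapes from biased
    umbrella-sampling time series by the weighted histogram analysis method
    (WHAM) with Monte Carlo bootstrap errors, traces minimum-energy paths and
    stationary points on the reconstructed grids, applies dual-level cubic
    spline energy corrections, and screens reaction profiles of polymer-drug
    conjugates against a kinetic viability threshold via transition-state
    theory. Ships analytic surrogate landscapes and a biased Metropolis
    sampler so the whole pipeline runs without a molecular-simulation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
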
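Package: cardiotherm
Title: Cardiac Thermal Performance Assays for Larval Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of stepwise cardiac thermal-performance
    assays in larval fish. Generates per-larva heart-rate-vs-temperature
    profiles with clutch and incubation-temperature structure, estimates
    per-individual thermal indices (Arrhenius breakpoint temperature T_AB,
    peak temperature T_peak, arrhythmia temperature T_Arr, and heart-rate
    metrics) from measured or simulated series, and performs the
    population-level inference: random-intercept mixed models, logistic
    threshold curves with 10/50/95 percent inverse prediction, kernel-density
    overlays, delta-N overlay statistics, and penalized-spline decline
    breakpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    mgcv,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
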
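Package: coldharvest
Title: Annual Time-Series Estimation of Cold- and Heat-Related Mortality
    Beyond Short-Term Displacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how much of cold- and heat-associated
    mortality is short-term displacement ("harvesting") of deaths among the
    frail.  Builds autumn-anchored 52-week annual series of death counts and
    degree-day temperature exposures from daily data, fits the annual
    quasi-Poisson regression with natural-spline trend, influenza-proportion
    and step-change adjustment, fits the comparative week-level conditional
    quasi-Poisson (time-stratified case-crossover) model with lagged cold,
    and runs a sensitivity grid over distributional family, trend
    flexibility, temperature threshold, extra steps and influenza control.
    Includes a synthetic daily-data generator with known acute temperature
    effects and a controllable mortality-displacement mechanism (displaced
    fraction and horizon), so that the annual design's ability to detect
    only displacement beyond the year can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    splines,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
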
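Package: collempop
Title: Pesticide Exposure, GUTS-RED Survival and Collembolan Population
    Simulation in a Vertical Soil Column
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples time-dependent predicted environmental concentrations
    (PEC) of pesticides in soil with toxicokinetic-toxicodynamic survival
    models (GUTS-RED, stochastic-death and individual-tolerance variants),
    mixture-effect rules (independent action and concentration addition),
    and an individual-based model of a Folsomia candida population living
    in a vertical soil column. Individuals move between soil layers, so
    each animal accumulates its own exposure history; toxicant mortality
    is sampled by inverse-CDF fate draws. Includes maximum-likelihood
    calibration of GUTS-RED parameters from standard survival test data
    with bootstrap confidence intervals, scenario file readers, tidy
    result writers, diagnostic plots and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
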
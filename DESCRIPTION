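Package: thermload
Title: Thermal Load Sensitivity Simulation for Vulnerable Plant Life Stages
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to model heat-failure risk of early plant life stages
    (pollen, imbibed seeds, seedlings) from thermal death time (TDT) curves
    and height-stratified microclimate temperature series. Provides TDT
    curve evaluation and least-squares fitting, cumulative heat-injury
    dynamics with an Arrhenius-type repair function, a simple vertical
    temperature-excess profile above the soil surface, a synthetic weather
    generator (diurnal cycles, heatwaves, rain days), Monte Carlo population
    simulation of heat failure probability, and a config-driven pipeline
    with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
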
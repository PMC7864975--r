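Package: sibflux
Title: Upscaling Carbon Emission from Inland Waters Across Permafrost Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regional upscaling of carbon dioxide and methane
    evasion from lakes, ponds, rivers and streams across a permafrost
    gradient. Converts partial-pressure observations to areal emission
    rates via Henry's law with chemical enhancement, extrapolates water
    surface areas below observation cutoffs with Pareto tail models,
    performs permafrost-zone-stratified Monte Carlo upscaling with
    latitude-dependent ice-free season lengths, propagates uncertainties
    in quadrature, and assembles a regional carbon budget comparing
    inland-water emission with terrestrial net ecosystem exchange,
    riverine export, and coastal sea uptake. Includes a calibrated
    synthetic landscape generator so the full pipeline runs and is
    testable without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
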
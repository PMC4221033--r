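Package: alborun
Title: Frontal Plankton Production in an Idealized Jet-Gyre Circulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale coupled biophysical model of plankton production
    at an ocean front, configured for an Alboran Sea-like jet-double gyre
    circulation. A four-compartment nitrogen-based NPZD (nutrient,
    phytoplankton, zooplankton, detritus) model is transported by a
    prescribed, discretely divergence-free meandering-jet flow with
    localized ageostrophic upwelling cells on the jet flanks. Includes a
    synthetic flow generator calibrated to observed Alboran kinematics,
    a conservative flux-limited tracer transport scheme, a nutrient-starved
    scenario builder, a 0-D box-model verification harness, and diagnostics
    for euphotic-layer inventories, transects, and nitrogen budgets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    deSolve,
    graphics,
    grDevices,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
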
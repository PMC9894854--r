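Package: salpflux
Title: Salp Bloom Carbon Export Budgets from Net Tows, Sediment Traps and
    Thorium-234
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles biological-carbon-pump budgets for Lagrangian ocean
    process studies dominated by salp (Salpa thompsoni) blooms. Converts
    net-tow records into size-binned areal abundance and biomass, estimates
    salp grazing from gut pigments with a gut-passage-time model and fecal
    pellet egestion by two independent methods, computes particulate organic
    carbon fluxes from drifting particle-interceptor traps with power-law
    depth attenuation and pellet morphometrics, estimates export from
    238U:234Th disequilibrium under steady-state and non-steady-state
    assumptions, derives phytoplankton growth and microzooplankton grazing
    from two-treatment dilution experiments with photoacclimation
    correction, and combines the pieces into export-efficiency metrics
    (Ez ratio, T100 flux transmission, pump efficiency). Ships a synthetic
    cycle generator with recorded ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
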
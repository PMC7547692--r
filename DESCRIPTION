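Package: socscape
Title: Coupled Soil Organic Carbon and Landscape Co-Evolution Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Process-based simulation of the co-evolution of soil organic
    carbon (SOC) and landscape form in gullied loess watersheds. Couples a
    three-pool (litter/humus/microbial biomass) vertical SOC turnover model
    with Exner-equation landscape evolution driven by hillslope diffusion
    and detachment-limited overland-flow sediment transport, moving
    surface-layer SOC with the sediment via an enrichment ratio. Includes
    synthetic generators for gullied and consolidated-gully watershed
    inputs (terrain, monsoonal daily precipitation, seasonal NDVI-driven
    litter input, exponential-with-depth initial SOC profiles), per-cell
    lateral/vertical carbon flux ledgers, carbon sink/source zoning,
    intra-annual flux climatologies, land-management scenario sweeps over
    litter input and surface carbon residence time, and linear areal
    upscaling of per-area rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    stats,
    graphics,
    tools,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
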
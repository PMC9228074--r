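Package: kbafootprint
Title: Trade-Linked Accounting of Biodiversity Loss from Land Use in
    Key Biodiversity Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hybrid physical/monetary multiregional input-output (MRIO)
    modelling of land use embodied in consumption, spatial allocation of
    consumption-based land use onto raster grids, conversion of land
    occupation into potential global species loss via ecoregion-level
    characterization factors, splitting of losses inside and outside key
    biodiversity areas (KBAs), embodied-trade flow accounting, final-product
    attribution, and a four-factor multiplicative decomposition of
    country-level KBA losses with contribution-to-variance analysis.
    Includes a synthetic-world generator producing balanced toy economies,
    land-use rasters, characterization factors and KBA masks with planted
    ground truth, so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
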
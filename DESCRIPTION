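Package: soilcapital
Title: Soil Natural Capital Accounting from Land Cover, Erosion and Soil
    Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds SEEA-style (System of Environmental-Economic Accounting)
    biophysical accounts for soil natural capital. Reclassifies CORINE-coded
    land-cover grids to the 14 interim SEEA land-cover classes, computes
    epoch-to-epoch change matrices with minimum-mapping-unit filtering, and
    assembles extent accounts (opening area, managed and natural expansion or
    regression, closing area). Builds per-land-cover soil mass-balance
    accounts from soil-formation rate bounds, gross rill-and-sheet erosion
    rates and a sediment-delivery partition of eroded mass into on-land
    redeposition and loss to watercourses. Classifies topsoil point samples
    (LUCAS-style) into peat, organo-mineral, humus-mineral and mineral
    organic-carbon classes and six pH classes, and cross-tabulates condition
    area by land cover and by land-cover change. A synthetic-data generator
    produces patchy categorical land-cover grids evolving under a Markov
    transition matrix, per-cover soil-sample distributions and
    peat-probability surfaces, so the whole pipeline is testable by parameter
    recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    tiff
Config/testthat/edition: 3
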
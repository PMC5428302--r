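Package: fugrid
Title: Gridded Level-IV Fugacity Modelling of Semivolatile Pollutant Fate
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A gridded, daily-time-step, dynamic (level-IV) fugacity
    multimedia fate and transport simulator for semivolatile industrial
    pollutants such as the lighter polychlorinated biphenyls. Each grid
    cell couples a two-layer atmosphere, a water column with sediment,
    and six land-use soil types resolved in four vertical layers;
    cells exchange air mass by wind-driven upwind advection. Includes
    air-soil exchange diagnostics (fugacity fraction), leaching potential,
    secondary-emission factors for non-source areas, a mass-conservation
    audit, Pearson model evaluation, and a seeded synthetic-data module
    for grids, meteorology, land surfaces and emission inventories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
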
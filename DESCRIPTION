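Package: canopycarbon
Title: Tree-Centric Forest Carbon Mapping from Airborne Laser Scanning and
    Hyperspectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tree-centric pipeline for mapping above-ground forest carbon.
    Individual tree crowns are delineated from height-normalized airborne
    laser scanning point clouds by local-maxima seeding and region growing on
    a smoothed canopy height model; tree species are recognised from
    hyperspectral pixels with a support vector machine after Jeffries-Matusita
    driven sequential floating feature selection; stem diameter is estimated
    from crown height and area by nonlinear median quantile regression; and
    per-tree biomass and carbon are aggregated into plot summaries and carbon
    density rasters at any grain, with a hidden-tree correction for
    understorey stems invisible to crown delineation. A synthetic conifer
    stand simulator (trees, point clouds, hyperspectral cubes, field
    inventories) makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    kernlab,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
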
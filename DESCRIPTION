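Package: buteoABM
Title: Agent-Based Simulation of Common Buzzard Territory Formation on
    Land-Cover Rasters
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An individual-based model of territory settlement by the
    common buzzard (Buteo buteo) on categorical land-cover rasters. Virtual
    birds sequentially claim a woodland roost and flood-fill whole patches
    of rough-ground and meadow until resource-area requirements estimated
    by Resource-Area-Dependence Analysis (RADA) are met, yielding emergent
    maximum abundance and distribution. Includes meadow-to-woodland
    landscape-change scenarios, percentage convex-polygon home-range
    metrics with pairwise overlaps, pattern-oriented calibration of forage
    search distances, Morris elementary-effects screening and full
    factorial sensitivity analysis, rank-based comparison statistics, a
    synthetic-landscape generator, ESRI ASCII grid input/output and a
    configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'buteoABM-package.R'
    'geometry.R'
    'rangeMetrics.R'
    'resourceMap.R'
    'engine.R'
    'calibration.R'
    'stats.R'
    'scenario.R'
    'raster_io.R'
    'pipeline.R'
    'sensitivity.R'
    'synthetic.R'
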
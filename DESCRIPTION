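Package: firepriority
Title: Multi-Criteria Spatial Prioritization of Post-Fire Restoration Areas
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reproducible raster pipeline that prioritizes burned landscapes
    for post-fire vegetation restoration by overlaying three boolean criteria
    on a shared analysis grid: repetitive fires (a pixel burned in two or more
    years of a multi-year burned-area record), steep terrain (Horn-method
    slope strictly greater than 15 degrees, derived from a fine-resolution
    DEM and aggregated to the analysis grid by area-weighted averaging), and
    location inside protected areas (polygon rasterization by the
    pixel-center rule). Pixels meeting at least two criteria form a
    preselection map; pixels meeting all three form the final priority map,
    which is tabulated by administrative region into exact pixel-count areas.
    Includes a synthetic-scenario generator with planted ground truth for
    end-to-end validation, plain-text raster (ESRI ASCII grid) and GeoJSON
    interfaces, and a configuration-driven pipeline runner with a thin
    command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'grid-core.R'
    'fire-history.R'
    'firepriority-package.R'
    'geometry.R'
    'io-geojson.R'
    'io-raster.R'
    'terrain.R'
    'protected.R'
    'prioritize.R'
    'synthetic.R'
    'pipeline.R'
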
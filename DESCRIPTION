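Package: corridorUD
Title: Migration-Corridor Utilization Distributions and Wind-Energy Hazard Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates population-level utilization distributions (UDs) for
    migratory raptors from GPS telemetry using a dynamic Brownian bridge
    movement model with sliding-window BIC changepoint estimation of the
    motion variance, extracts directional migration segments from tracks,
    combines per-segment UDs into a weighted population surface, ordinates
    cells into use categories, and overlays wind turbines and wind power
    class rasters to produce hazard-overlap reports. Includes a synthetic
    telemetry, turbine-field and wind-power-class generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
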
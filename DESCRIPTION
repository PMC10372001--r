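Package: croplandNdep
Title: National-Scale Atmospheric Nitrogen Deposition on Cropland
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds national annual time series (1961-2020) of atmospheric
    nitrogen deposition on cropland from gridded deposition, emission and
    cropland-area inputs. Provides a regular latitude/longitude grid data
    model with spherical cell areas, conservative fine-to-coarse regridding
    and fractional country masks; adapters for decadal-to-annual cropland
    reconstructions (HYDE-style year mapping, LUH2-style maximum crop-type
    fraction); a per-grid-cell gap-filling estimator that interpolates
    deposition linearly in time between decadal anchors and regresses
    deposition on co-located emission for the remaining years;
    cropland-area-weighted aggregation to country rates and totals;
    precipitation-chemistry station arithmetic for wet-deposition
    validation; and a nitrogen-use-efficiency sensitivity analysis across
    deposition products. Includes a seeded synthetic-world generator with
    known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
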
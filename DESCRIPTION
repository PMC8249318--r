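Package: flowerpheno
Title: UAV Multispectral Flowering Phenotyping for Canola Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for estimating canola flowering intensity and
    seed yield from multi-date UAV multispectral reflectance imagery.
    Computes normalized-difference vegetation index maps (NDVI, NDYI, GNDVI,
    NDRE), separates flowering from non-flowering pixels by thresholding the
    normalized difference yellowness index, counts flowering pixels per field
    plot by zonal extraction, integrates flowering progress over the season
    with the baseline-adjusted area under the flowering progress curve
    (AUFPC), and fits the two calibration layers: zero-intercept regression
    of manual flower counts on flowering pixel counts per image date, and
    linear regression of seed yield on AUFPC. A synthetic field-campaign
    generator with full ground truth makes every stage testable without
    field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    EBImage,
    optparse
Config/testthat/edition: 3
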
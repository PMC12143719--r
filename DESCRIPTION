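Package: forestknn
Title: Forest Attribute Mapping by k-Nearest-Neighbour Imputation of
    Inventory Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A toolkit for landscape-scale mapping of timber volume,
    above-ground biomass and conifer proportion from national forest
    inventory plots and 10 m satellite image composites.  Plot spectral
    signatures are extracted as area-weighted means over a 100 m2
    circular footprint, screened for cloud contamination and
    post-measurement canopy loss, split into mapping and validation sets
    by a deterministic every-third rule, and imputed to pixels with a
    multivariate inverse-distance-weighted k-nearest-neighbour model
    (k = 7 by default) that also yields a per-pixel standard-deviation
    uncertainty layer.  Output maps are encoded as uint16 GeoTIFF tiles
    with sentinel values for non-forest and no-data, and validated with
    RMSE, bias, R-squared and binned-bias reports.  A synthetic-scene
    generator with a known ground truth supports end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
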
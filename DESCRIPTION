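Package: stomaspace
Title: Spatial Point-Pattern Analysis of Stomatal Patterning on the Leaf Epidermis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how clonal (mosaic) sectors on a cotyledon influence
    stomatal positioning from 2D coordinate data exported from confocal
    segmentation. Provides offset-ring stomatal density accounting around
    sector outlines, a stomata-sector spatial correlation function evaluated
    against ensembles of complete-spatial-randomness null points confined to
    the cotyledon outline, a Landy-Szalay-type stomata-stomata
    autocorrelation estimator, reference pattern simulators (uniform,
    clustered, ringed, hard-core spaced), the associated hypothesis tests,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    polyclip,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    spatstat.geom,
    withr
Config/testthat/edition: 3
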
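Package: palatelev
Title: Quantitative Analysis of Murine Palatal Shelf Elevation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical and image-based quantification of palatal shelf (PS)
    elevation in mouse embryos. Provides staging analytics for time-restricted
    embryo cohorts (stage tabulation, integer percentage summaries, exact
    sex and strain contrasts, elevation-window estimation, side-preference
    tests), self-contained exact statistics (two-sided Fisher exact test,
    exact binomial test, two-tailed Welch t-test), nuclear morphometry on
    two-channel fluorescence sections (segmentation, ellipse-moment
    orientation, marker positivity), axial circular statistics including the
    2D nematic order parameter S, regional deviation-from-mean metrics for
    KI-67 and p-MLC, and a synthetic-data generator with ground truth so
    every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
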
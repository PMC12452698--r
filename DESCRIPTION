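Package: matt
Title: Transillumination-Based Tracking of Bony Landmark Motion Under
    Soft Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Measures the displacement of a transilluminated bony landmark
    (such as the lateral femoral epicondyle lit from within by an
    arthroscopic light source) beneath intact myofascial tissue in video
    recordings.  Detects the bright "light hollow" in each frame by
    intensity thresholding and geometric filtering, tracks its
    intensity-weighted centroid, calibrates pixels to millimetres from an
    in-frame ruler, and computes signed displacements relative to
    annotated fascial border lines under a negative-on-crossing
    convention.  Includes a synthetic-scene generator with known ground
    truth for validation, and a layered-tissue Monte Carlo photon
    transport model (Henyey-Greenstein scattering, Fresnel boundaries,
    Russian roulette) to study how tissue thickness spreads and biases
    the transilluminated spot.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
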
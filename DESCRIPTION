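Package: msialign
Title: Landmark Co-Registration and Spot-Level Integration of Mass
    Spectrometry Imaging with Visium Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Co-registers spatially resolved transcriptomics (10x Visium)
    and mass spectrometry imaging (MSI) metabolomics from the same or
    consecutive tissue sections into a common coordinate frame. Reads and
    writes Space Ranger-style bundles, preprocesses peak-by-pixel MSI
    tables (TIC normalisation, peak deduplication, pixel quality filters),
    builds data-generated images for landmark selection, estimates affine
    and thin-plate-spline transforms from landmark pairs, aggregates MSI
    pixels into one observation per Visium spot, and scores alignment by
    tissue/background label agreement. Includes a synthetic paired-data
    generator with known ground-truth geometry and a landmark-subsampling
    benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    png,
    purrr,
    RANN,
    readr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
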
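Package: frondkit
Title: Duckweed Plate-Image Quantification, Growth Modelling and Inventory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image-based duckweed (Lemnaceae) growth assays: detects a
    petri dish in a top-down photograph, segments green frond pixels, and
    converts pixel counts into calibrated frond area in square millimetres;
    analyses frond-dissection photographs for frond diameters and fronds per
    ramet; turns per-dish area series into growth curves, dose-response (Hill)
    fits, relative growth rates, storage-viability decay fits and Tukey
    significance groupings; and provides a small file-backed inventory layer
    with item lineage, plan-scoped treatments and key-value data associations.
    A synthetic-data generator renders plate and dissection images and
    simulates dose-response, recovery and storage experiments with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    minpack.lm,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse,
    withr
Config/testthat/edition: 3
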
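Package: morphotherm
Title: Endoscopic Tumour Morphometry, Photothermal Curve Fitting and
    Plate-Assay Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for nanoplatform therapy studies
    of orthotopic colorectal tumours. Turns binary lesion segmentation masks
    into per-instance morphometry (connected-component labelling, Moore
    boundary tracing, monotone-chain convex hulls, rotating-calipers maximum
    Feret diameter), calibrates pixel distances to physical units with linear
    standard curves, fits cooling-curve time constants and photothermal
    conversion efficiency, fits first-order decay half-lives, and computes
    the standard plate-assay statistics (haemolysis rate, cell viability,
    organ and tumour indices, mass fractions, hydrogen-sulfide quantification
    and reduction rates). Includes a synthetic-data generator producing every
    input with known ground truth for validation.
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
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
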
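Package: iba1quant
Title: Morphometry and Marker Quantification for Iba1-Positive Myeloid Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-cell image quantification of brain myeloid (Iba1-positive)
    cells in two-channel confocal fluorescence stacks: maximum-intensity
    projection, rolling-ball background subtraction, smoothing and unsharp
    masking, constant-threshold segmentation, area/circularity morphometry
    with explicit activation-state gates (ramified, hypertrophic, ameboid),
    masked marker-intensity measurement with a soma versus ramification
    decomposition, and relative qPCR quantification by the delta-delta-CT
    method with multi-reference-gene normalization. Includes a synthetic
    two-channel scene generator with per-cell ground truth so the whole
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
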
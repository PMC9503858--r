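Package: planardose
Title: Fast Bone-Marrow Dosimetry from a Single Planar Whole-Body Scan
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Approximated personalized dosimetry for radionuclide therapy
    from a single post-therapy planar whole-body scintigraphy acquisition.
    The geometric-mean image is segmented automatically into high- and
    low-uptake compartments by a threshold sweep over the number of uptake
    foci; cumulated activities are reconstructed from the single time point
    via assumed two-compartment kinetics and a self-calibrated counts ratio;
    the bone-marrow dose is assembled in the MIRD formalism from
    configurable S-factor tables (OpenDose-style CSV exports). The classical
    Benua/Lassmann blood-based dose, with exponential and bi-exponential
    fits of blood and whole-body retention curves, is included as the
    reference comparator, together with a synthetic planar-phantom
    generator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
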
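Package: epiquant
Title: Quantitative Morphometry and Immunofluorescence Analysis of
    Stratified Squamous Epithelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying histology and immunofluorescence images of
    stratified squamous epithelium (e.g. paired inner/outer foreskin
    sections): epidermis segmentation from red-channel autofluorescence,
    Feret-diameter based thickness and parakeratosis morphometry,
    tight-junction stain coverage, mean intensity and polarization scoring
    with isotype-control subtraction, size-gated detection of CD4+/CCR5+
    cells with per-subject background correction, explant analyte-ratio
    analysis with hemoglobin contamination filtering, and paired Wilcoxon
    signed-rank inference with Benjamini-Hochberg false discovery rate
    control over a declared comparison family. Includes a ground-truthed
    synthetic section and cohort generator so the whole pipeline is testable
    without access to tissue scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    rlang,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
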
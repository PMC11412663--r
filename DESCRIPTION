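Package: ifcyto
Title: Multiplex Immunofluorescence Processing, Nucleus Segmentation and
    Cytometry Export
Version: 1.0.0
Authors@R:
    person("Iris", "Fontaine", email = "iris.fontaine@example.org",
           role = c("aut", "cre"))
Description: End-to-end processing of multi-channel immunofluorescence
    images: grid stitching of scanner tiles (with black-tile infill),
    rolling-ball background subtraction, contrast-limited adaptive
    histogram equalization (CLAHE), Difference-of-Gaussians nucleus
    segmentation with ISODATA thresholding, per-cell geometry and
    intensity measurement including corrected total cell fluorescence
    (CTCF), and export of single-cell tables to TSV, XLSX and FCS 3.1 so
    downstream analysis can be done in any cytometry software. Also
    provides an instance-segmentation benchmark (IoU-threshold matching,
    precision/recall/Jaccard/F-measure curves, percent detected objects
    and efficacy aggregation) and a seeded synthetic nuclei-image
    generator with ground-truth masks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
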
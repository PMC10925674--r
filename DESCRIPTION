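Package: ihcscore
Title: Nuclear Positivity Scoring for DAB Immunohistochemistry Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic detection of nuclei in immunohistochemical (DAB,
    e.g. ki67) microscopy images, three-level stain-intensity
    classification with a trainable RBF-kernel support vector machine,
    partition of an epithelium region of interest into basal, medial and
    superior strata, and per-stratum positivity quantification. Includes
    a region-based detector (CIELAB preprocessing, multi-level Otsu
    thresholding, seeded k-means colour clustering and distance-transform
    splitting of touching nuclei), an edge-based detector (Canny with
    automatic hysteresis thresholds), overlay persistence to XML, CSV
    results export, detection and classification evaluation metrics, and
    a deterministic synthetic-scene generator with ground truth for
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    xml2,
    png,
    tiff,
    grDevices,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
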
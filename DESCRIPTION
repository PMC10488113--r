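Package: myoslice
Title: Viability Classification and Structural Analysis of Cardiomyocytes
    in Myocardial Slice Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated analysis of multi-channel confocal images of
    myocardial tissue slices. Segments single cardiomyocytes by a
    watershed transform on the Euclidean distance map of the thresholded
    wheat germ agglutinin (WGA) signal, classifies each cell as viable
    (ryanodine receptor positive), dead (dextran positive), double
    positive or double negative from per-segment pixel fractions, and
    quantifies transverse tubular system geometry, nucleus morphology and
    the spectral regularity of ryanodine receptor clusters. Includes a
    synthetic slice-image generator with per-cell ground truth, diagnostic
    accuracy evaluation (sensitivity, specificity, predictive values, ROC)
    of the ryanodine receptor stain against the dextran death assay, and
    force-versus-viability regression utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
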
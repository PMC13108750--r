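Package: spheroflux
Title: Spheroid Morphometry and Extracellular Flux Analysis for 3D Tumor Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for metabolic measurements in 3D tumor spheroids:
    Chan-Vese level-set segmentation of brightfield well images with circularity,
    yield, aggregation-kinetics and well-centering quality metrics; Mito Stress
    Test parameterization of oxygen consumption rate (OCR) traces (basal, ATP-linked,
    maximal, spare respiration, proton leak, coupling efficiency); and evaluation of
    normalization strategies (experiment-median, seeded cell number, projected area)
    by Pearson correlation and relative standard deviation. Includes seeded synthetic
    generators for images, plates, OCR traces and multi-experiment designs so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rtsne,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
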
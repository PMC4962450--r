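Package: spectropath
Title: Pseudo-HE Staining of Multimodal Microscopy Images and Raman
    Spectral Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage optical pathology screening toolkit. Stage one
    translates label-free nonlinear multimodal microscopy images (CARS,
    TPEF and SHG channels) into computational hematoxylin-eosin
    ("pseudo-HE") images via partial least squares colour regression, a
    linear discriminant nuclei overlay, and a k-means derived background
    weighting mask. Stage two performs spectral histopathology on Raman
    hyperspectral maps of suspicious regions: SNIP baseline subtraction,
    vector normalisation, PCA compression, cluster-based annotation
    transfer, weighted k-nearest-neighbour classification and
    individual-out cross-validation with confusion statistics. Includes
    synthetic-data generators for both modalities so the whole pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    tiff,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mixOmics,
    withr
Config/testthat/edition: 3
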
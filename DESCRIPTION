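Package: akdetect
Title: Erythema-Based Detection of Actinic Keratoses in Clinical Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects erythematous actinic keratosis lesions in standardized
    clinical photographs of sun-damaged skin. The detector transforms an RGB
    photograph to YCbCr, takes the mean of the chroma channels as an erythema
    intensity map, smooths it with an edge-preserving guided filter, isolates
    small bright peaks with a top-hat by morphological reconstruction, and
    binarizes them with hysteresis thresholding. The package also provides the
    lesion-level co-localization evaluation protocol (centroid containment
    matching, confusion counts, sensitivity and positive predictive value),
    pixel-level F2-driven grid search with nested leave-one-volunteer-out
    cross-validation for parameter tuning, Welch and Pearson group statistics,
    and a synthetic skin-field generator with known ground truth for
    validating every stage without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
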
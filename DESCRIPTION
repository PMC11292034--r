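Package: panicletraits
Title: Non-Destructive Trait Extraction from Intact Rice Panicle Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts yield-component traits from photographs of intact rice
    panicles without threshing: occlusion-calibrated grain counting via a
    panicle morphology index (PMI), grain length/width/aspect-ratio
    morphometry from screened detections using minimum-area rotated bounding
    rectangles, and panicle length measured as the longest bottom-to-top
    path on the panicle skeleton found by A* search. Pixel measurements are
    converted to millimetres with a red circular calibrator of known radius.
    Includes a ground-truthed synthetic scene generator and detector
    simulator so the whole pipeline is testable without field images, plus
    evaluation metrics (MAPE, MAE, RMSE, R-squared, accuracy, mAP50).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    EBImage,
    png,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
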
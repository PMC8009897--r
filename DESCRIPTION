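Package: spinaxis
Title: Automated Spinal Curvature Estimation from AP Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computerized estimation of scoliotic spinal curvature from
    antero-posterior spine radiographs. Extracts the spinal column by optimum
    global thresholding and morphological cleanup, traces its boundary, derives
    the medial axis (MA) and central sacral line (CSL), automatically detects
    scoliotic curves with their superior/inferior end vertebrae and apical
    vertebra from the MA-CSL displacement signal, and measures curvature by the
    Cobb, Ferguson, Greenspan-index and Diab constructions with severity
    grading. Includes a synthetic phantom generator with analytic ground truth
    for validation, and Cohen's kappa utilities for inter-rater landmark
    agreement studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    EBImage,
    igraph,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    tidyr,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
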
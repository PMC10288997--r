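Package: octamorph
Title: Microvascular and Foveal Avascular Zone Morphometry for En-Face OCTA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantification pipeline for en-face optical coherence tomography
    angiography (OCTA) of the macula. Provides local-phase vessel enhancement
    and region-based active-contour segmentation of the retinal microvasculature
    and the foveal avascular zone (FAZ), skeleton-graph decomposition
    (bifurcation detection, branch extraction, arc-chord tortuosity), twelve
    morphometric biomarkers (FAZ area/circularity/axial ratio/roundness/
    solidity, orientation-ellipse direction area and ratio, tortuosity, vessel
    area and length density, box-counting fractal dimension, bifurcation
    count), ETDRS eight-sector sub-regional quantification, and case-control
    statistics (summary and sample t-tests, covariate-adjusted logistic
    regression, three-level sector significance maps). A synthetic vascular
    tree and cohort simulator with exact ground truth supports validation
    without patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
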
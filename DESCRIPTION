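Package: metquant
Title: Nucleus Tracking and Apicobasal Polarity Profiling for Embryonic Epithelial Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis for mesenchymal-to-epithelial
    transitions in embryonic tissue, built around two pipelines. A 4D
    nucleus-tracking pipeline estimates and compensates global embryo drift,
    detects fluorescent nuclei with an anisotropy-aware scale-normalized 3D
    Laplacian-of-Gaussian filter with strongest-minima pruning, links
    detections frame to frame by gated linear assignment, and derives
    per-track velocity, directional persistence, and neighbour coordination
    with embryo-level and condition-level statistics. An apicobasal
    profiling pipeline preprocesses fixed images (8-bit conversion,
    inversion, sliding-paraboloid background subtraction, stacked-histogram
    thresholding), extracts wide-line apical-to-basal intensity profiles,
    and quantifies windowed peak amplitude and full width at half maximum.
    Ground-truthed synthetic movie and epithelium generators make every
    stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
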
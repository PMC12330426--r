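Package: connage
Title: Brain Age from Static and Dynamic Functional Network Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for functional brain-age modeling from independent-component
    time courses: post-ICA denoising (polynomial detrending, nuisance
    regression, robust outlier clipping, zero-phase low-pass filtering),
    static and tapered sliding-window dynamic functional network connectivity
    (FNC), wide-brain and per-network brain-age regressors (ridge baseline,
    graph-convolutional network on static FNC, bidirectional LSTM on the
    dynamic FNC window sequence), brain-age gap (BAG) computation, and
    covariate-adjusted general-linear-model association of BAGs with cognitive
    scores under Benjamini-Hochberg false-discovery-rate control. Includes a
    synthetic-cohort generator with known ground-truth aging, site, diagnosis
    and cognition structure so the full pipeline is testable without
    access-controlled neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
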
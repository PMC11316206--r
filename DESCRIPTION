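Package: megnet
Title: Resting-State MEG Envelope Connectivity and Multi-Threshold Network
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for resting-state magnetoencephalography
    parcel time series: band-limited Hilbert envelope extraction,
    leakage-corrected (orthogonalized) amplitude envelope correlation,
    proportional-threshold weighted graph metrics (modularity, global
    efficiency, 2017-corrected mean local efficiency), multi-threshold
    max-statistic permutation correction (MTPC) for group comparisons,
    and regression of network metrics against cognitive scores.  Includes
    a synthetic cohort generator with planted modular envelope networks
    and known metric-cognition relationships so every stage is testable
    without access to patient recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
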
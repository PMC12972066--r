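Package: fretburst
Title: Burst Analysis of Trapped Single-Molecule FRET Photon Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of two-channel (donor/acceptor) photon-count
    time traces from single-molecule FRET experiments in which individual
    molecules are held for hundreds of milliseconds, e.g. in an
    anti-Brownian electrokinetic (ABEL) trap. Provides background correction,
    burst filtering and proximity-ratio (PR) computation; photon re-coloring
    Monte-Carlo null models ("static homogeneity" and "static heterogeneity");
    burst-variance analysis against the shot-noise limit; burst-edge-aware
    intensity and PR correlation functions; median-split recurrence analysis
    of PR distributions; burst-level bootstrap confidence intervals; a
    ground-truth-labeled synthetic photon-trace generator; and mean-squared
    displacement estimation of diffusion coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
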
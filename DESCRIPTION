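Package: slowwave
Title: Slow-Oscillation and Slow-Wave Dynamics from Multichannel Cortical LFP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cortical slow-oscillation recordings:
    multiunit activity (MUA) estimation from normalized high-frequency
    (200-1500 Hz) LFP spectral power, threshold-based Up/Down state detection
    with slow-oscillation metrics (durations, regularity, firing rates,
    transition slopes, band power), slow-wave reconstruction across
    multielectrode arrays with exact thin-plate-spline time-lag interpolation
    and propagation-speed maps, PCA-plane entropy of wavefront patterns, and
    Pearson functional-connectivity graphs with Louvain modularity,
    characteristic path length and functional complexity. Includes a
    statistical generator of multichannel LFP with known ground truth
    (state sequences, band content, propagating wavefronts, block-structured
    correlations) so every stage is testable end to end, plus cohort-level
    nonparametric group comparison and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
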
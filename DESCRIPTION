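Package: axontrack
Title: Tracking Single Action Potentials Across Axonal Arbors on
    High-Density Microelectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and timing of individual axonal action potentials
    recorded on high-density microelectrode arrays. Implements
    spike-triggered-average electrical footprints with axon-initial-segment
    localization, noise-covariance-whitened multi-electrode matched filters
    with an analytic detection threshold, sub-sample arrival-time estimation
    by sinc interpolation, and the downstream conduction statistics:
    excitability regimes and voltage normalization, activation
    latency/jitter decomposition, propagation-velocity regression, linear
    accumulation of propagation jitter with axial distance, and
    high-frequency (100 Hz) stimulation-train effects. A seeded synthetic
    HD-MEA recording generator with full ground truth supports end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
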
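Package: mesorank
Title: Mesoscale Functional Network Dynamics from Multi-Region Spike Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for chronic multi-region single-unit
    recordings in a visual Go/No-Go task: behavioral d-prime staging of
    trials into early and expert learning stages, single-unit activity onset
    timing and regional temporal-compression statistics, cross-correlation
    (total spiking probability edge, TSPE) functional connectivity with
    jitter-surrogate significance and excitatory short-delay filtering,
    region-level 1-10 rank dynamics of functional input/output strength,
    bootstrap-balanced auROC stimulus-selectivity classification, and the
    correlation between a region's network rank and its stimulus-encoding
    peak time. Includes a synthetic spiking-cohort generator with planted
    directed connectivity, region-specific response latencies and a learning
    trajectory, so every stage is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
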
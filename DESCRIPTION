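Package: cracm
Title: Analysis of Optogenetic Circuit-Mapping Slice Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for channelrhodopsin-assisted circuit mapping (CRACM)
    experiments in acute brain slices. Detects optogenetically evoked
    inhibitory postsynaptic currents (oIPSCs) in voltage-clamp sweeps and
    classifies per-cell monosynaptic connectivity, quantifies suppression
    of tonic pacemaker firing from loose-seal recordings during light
    trains, measures short-term plasticity of train-evoked responses
    (paired-pulse and last/first ratios), and computes circuit-level
    cohort summaries with Kruskal-Wallis tests, two-stage adaptive FDR
    control, and location-based connectivity regression. Includes a
    synthetic patch-clamp recording generator with known ground truth so
    every analysis stage can be validated without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
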
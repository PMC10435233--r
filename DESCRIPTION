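Package: optophysio
Title: Quantification of Optogenetically Manipulated Cardiac and Locomotor
    Physiology in Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Video-derived physiology analysis for optogenetic experiments in
    larval zebrafish: heartbeat detection from region-of-interest luminosity,
    cardiac-arrest latency and resumption metrics, arrest-time ratios for
    pharmacological blockade, atrioventricular conduction delay, delta-F/F
    calcium trace normalization, tail-bout locomotion metrics, and per-larva
    group statistics. Includes a synthetic-data generator built on a bistable
    opsin two-state photostate model that drives simulated heart, tail, and
    calcium signals with known ground truth, so every analysis stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    mgcv,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
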
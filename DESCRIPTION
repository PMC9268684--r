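Package: dgephys
Title: Unit Phenotyping and Behavioral Scoring for Dentate Gyrus
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracellular unit phenotyping for dentate gyrus recordings:
    spike-waveform features (trough-to-peak latency, afterhyperpolarization
    slope from the waveform first derivative), inter-spike-interval burst
    index, and a three-stage threshold classifier separating putative
    parvalbumin-expressing interneurons, wide-waveform interneurons, mossy
    cells and granule cells, including data-driven recovery of the bimodal
    afterhyperpolarization split point.  Also provides group-level firing
    statistics with normality gating (D'Agostino-Pearson, one-/two-way
    ANOVA with Bonferroni post hoc, Kruskal-Wallis with Dunn post hoc),
    current-clamp slice analysis (F-I curves, first action potential
    properties), chronic social defeat behavioral scoring (social
    interaction ratio, susceptible/resilient split, sucrose preference),
    and a seeded synthetic-data generator so the whole pipeline is testable
    end to end without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
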
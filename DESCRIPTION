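Package: duraCa
Title: Event-Based Analysis of Meningeal Macrophage Calcium Imaging and
    Dural Vasomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for in-vivo two-photon calcium imaging of meningeal
    macrophages in awake behaving mice. Provides rigid motion correction and
    temporal downsampling of two-channel movies, event-based detection and
    feature extraction of spatiotemporal Ca2+ events with perivascular niche
    assignment and propagation classification, frequency-domain clustering of
    cell activity, intercellular event synchronization analysis, two-state
    hidden Markov decoding of locomotion from wheel velocity, Radon-transform
    vessel diametry, lagged elastic-net generalized linear models coupling
    macrophage Ca2+ to vasomotion, and rule-based classification of acute and
    persistent Ca2+ responses to cortical spreading depolarization. A
    synthetic-data module generates movies, traces, and event tables with
    planted ground truth so every stage is testable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    glmnet,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
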
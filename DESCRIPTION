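Package: neoqeeg
Title: Quantitative EEG, Evoked Potentials and Neuropathology for Neonatal
    Hypoxic-Ischemic Encephalopathy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for preclinical neuroprotection studies in
    neonatal hypoxic-ischemic encephalopathy (HIE) models: EDF input/output,
    1-30 Hz quantitative EEG (band powers, 95% spectral edge frequency,
    normalized Shannon spectral entropy), entropy-and-amplitude-feature
    electrographic seizure detection with per-animal burden and onset
    summaries, flash visual evoked potential (VEP) averaging with P100
    latency/amplitude extraction, neocortical injury-pattern scoring and
    percent-damaged-neuron metrics, and the group-level statistical layer
    (Shapiro-Wilk, Levene, one-/two-way ANOVA with Tukey HSD, Kruskal-Wallis
    with Dunn post hoc, Welch tests from summary statistics). Includes a
    synthetic cohort generator that emulates three treatment arms
    (normothermia, molecular hydrogen, therapeutic hypothermia) on a
    compressible 48 h timeline so the full pipeline is testable without raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    emmeans,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
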
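Package: psgagree
Title: Inter-Scorer Agreement and Scoring-Time Analysis for Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify inter-scorer agreement and scoring-time
    differences between manual and computer-assisted (semi-automatic)
    polysomnography scoring. Annotations (sleep-stage hypnograms, leg
    movements, respiratory events, EEG arousals, oxygen desaturations) are
    read from EDF+-style annotation (TAL) streams or a plain tabular dialect,
    discretized onto task-specific mini-epoch grids restricted to the time in
    bed, and compared across scorer pairs with Cohen's kappa. Diagnostic
    indices (sleep efficiency, sleep onset latency, WASO, AHI, AI, HI, ODI,
    arousal index, and WASM2016 leg-movement indices) are derived per scorer
    and compared across scorers with the two-way absolute-agreement
    single-measures intraclass correlation ICC(A,1), including confidence
    intervals and significance tests against a prescribed baseline. Paired
    Wilcoxon signed-rank tests, Cohen's d effect sizes, Brown-Forsythe
    variance tests with mean normalization, and median scoring-time gain
    factors complete the comparison battery. A synthetic multi-scorer study
    generator with per-scorer corruption models makes the whole pipeline
    testable end to end, and a percentile-stratified recording-selection
    procedure reproduces the study-design stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
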
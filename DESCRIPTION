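Package: synapseflux
Title: Quantification of Glutamate Imaging, NMJ Fluorescence, Climbing and
    Lifespan Assays in Drosophila Amyloid Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative assays used in adult-onset Drosophila
    models of amyloid-beta toxicity. Converts iGluSnFR fluorescence traces to
    dF/F, detects glutamate release events and segments multi-peak bursts,
    and summarizes amplitudes and event rates per animal. Quantifies
    neuromuscular-junction immunofluorescence from confocal Z-stacks
    (rigid registration, maximum-intensity projection, background
    harmonization, mean ROI intensity). Implements the negative-geotaxis
    performance index, Kaplan-Meier curves, the two-group log-rank test, a
    stratified permutation test for genotype-by-induction interaction in
    survival, and one-way ANOVA with Tukey HSD. A synthetic-data module
    generates fluorescence traces and image stacks with ground-truth events,
    survival cohorts with known hazard structure, and trinomial climbing
    counts, so every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
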
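Package: adctrack
Title: Weekly Tumor Response Assessment from Diffusion-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for longitudinal response assessment of
    tumors (grossly involved lymph nodes) under chemoradiotherapy using
    diffusion-weighted MRI. Computes voxel-wise apparent diffusion coefficient
    (ADC) maps from multi-b-value acquisitions via the monoexponential decay
    model, isolates viable tumor by Boolean subtraction of cystic/necrotic
    regions of interest, summarizes first-order ADC histogram statistics
    (mean, median, percentiles, skewness, excess kurtosis), tracks weekly
    absolute and percent changes against the pretreatment baseline with a
    configurable early-change response rule, detects bimodal ADC histograms
    with a seeded Gaussian-mixture helper, and reports interobserver agreement
    (two-way random-effects ICC with 95% confidence interval) and Pearson
    correlation between functional and morphological change. Includes a seeded
    Rician-noise digital-phantom generator emulating weekly ADC and volume
    trajectories, plus minimal NIfTI-1 input/output so the full pipeline is
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
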
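Package: synredist
Title: Synapse Redistribution Modelling and Fiber-Volley-Normalised
    Evoked-Response Analysis for Adult Neurogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic, age-structured simulation of how a fixed pool of
    entorhinal-cortex synapses is redistributed from mature to adult-born
    dentate granule cells under control and enhanced-survival (Bax-deletion)
    conditions, together with the analysis pipeline used for simultaneous
    field and whole-cell evoked-response recordings: sweep averaging,
    saturation exclusion, fiber-volley binning, EPSC/FV and fEPSP/FV
    normalisation, paired-pulse ratios, spontaneous-event summaries, and the
    unweighted-means factorial ANOVA for unbalanced binned designs. Seeded
    synthetic-data generators emulate the statistical structure of the
    recordings so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
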
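Package: eodkit
Title: Electric Organ Discharge Waveform Features and Androgen-Response
    Expression Analysis
Version: 0.1.0
Authors@R:
    person("EOD", "Toolkit Authors", email = "eodkit@example.org",
           role = c("aut", "cre"))
Description: Tools for studying androgen-induced elongation of the electric
    organ discharge (EOD) in mormyrid electric fish. Implements EOD waveform
    preprocessing (baseline correction, peak-to-peak normalization, alignment,
    averaging), threshold-based pulse-bound detection, the standard waveform
    parameters (durations, phase landmarks, amplitude ratio, maximum P1 slope,
    P2 exponential decay constant), longitudinal acclimation checks and
    between-treatment inference (one-way ANOVA, Tukey HSD with compact letter
    display), TMM count normalization, a documented stand-in differential
    expression test with fold-change/FDR filtering and three-contrast pattern
    classification, multi-contrast rank-based gene-set enrichment with
    select-set rules, and candidate-gene derivation. A fully seeded synthetic
    data module (pulse cohorts with closed-form landmark truth,
    negative-binomial count matrices with planted differentially expressed
    genes, GMT gene-set libraries with planted enrichment) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
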
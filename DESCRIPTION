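Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for post-marketing pharmacovigilance analysis of FDA
    Adverse Event Reporting System (FAERS) quarterly files: case
    deduplication by CASEID/FDA_DT with deleted-case removal, reporting
    odds ratio (ROR) and Bayesian confidence propagation neural network
    (BCPNN) information-component screening with dual-threshold signal
    flagging, clinical priority scoring, signal-origin classification
    against comparator drugs, stratified modified-ROR subgroup analysis,
    logistic-regression risk-factor modelling, and Weibull time-to-onset
    characterization with failure-type classification.  A synthetic FAERS
    generator with planted drug-event associations, duplicates, deletions
    and Weibull onset times lets the whole pipeline be validated against
    known ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
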
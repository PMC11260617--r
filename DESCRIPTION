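Package: pvfaers
Title: Pharmacovigilance Signal Detection and Time-to-Onset Analysis for
    FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for disproportionality analysis of
    spontaneous adverse-event reports in the FDA Adverse Event Reporting
    System (FAERS) quarterly ASCII format: ingestion and case-level
    deduplication of the DEMO/DRUG/REAC/OUTC/THER/INDI tables,
    primary-suspect drug selection with synonym normalization, restriction
    to a system organ class through a PT-HLT-SOC term hierarchy, 2x2
    contingency tables with four signal-detection statistics (reporting
    odds ratio, proportional reporting ratio with chi-squared,
    gamma-Poisson shrinkage EBGM/EB05, and the Bayesian confidence
    propagation neural network information component) under a joint
    screening criterion, serious/non-serious severity comparisons, and
    Weibull time-to-onset characterization with failure-type
    classification.  A seeded synthetic FAERS emulator with a ground-truth
    manifest makes every stage testable without the multi-gigabyte FAERS
    download.
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
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
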
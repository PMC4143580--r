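Package: splicescreen
Title: PCR-Based Alternative-Splicing Screens and Multi-Reference qPCR
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for PCR-based alternative-splicing screening
    studies. Quantifies the percent splicing index (PSI) of alternative
    splicing events from capillary-electrophoresis peak tables, runs a
    two-stage screen (a pooled-RNA detection screen with a 10%-of-total-signal
    activity rule, then a per-subject validation screen) across four
    disease-by-genotype groups, performs the six intergroup Student t-test
    contrasts with false-discovery-rate correction and rule-based
    disease/mutation association calling, computes Fisher exact genotype
    association, and provides efficiency-corrected relative qPCR
    quantification normalized to the geometric mean of multiple reference
    genes (qBase-style CNRQ). A synthetic-cohort generator with a logit-normal
    splicing model, electrophoresis noise, pooled pre-amplified lanes and
    simulated Ct tables makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
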
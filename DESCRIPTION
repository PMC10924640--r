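Package: thrscore
Title: Intertumoral Heterogeneity Response Score for Solid Tumor Response Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intertumoral heterogeneity of treatment response in
    patients with multiple measurable solid tumor lesions. Implements RECIST 1.1
    sum-of-diameters response classification, the THRscore (the coefficient of
    variation of per-lesion percentage diameter changes, taken against the
    absolute mean), outcome-driven cutoff discovery by maximally selected rank
    statistics with repeated-subsampling consensus, Kaplan-Meier/Cox/log-rank
    survival analysis with restricted cubic spline dose-response, time-dependent
    ROC, censoring-weighted net reclassification and integrated discrimination
    improvement, panel-sequencing somatic variant filtering with tumor mutation
    burden, and a synthetic cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
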
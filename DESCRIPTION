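Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for pharmacovigilance signal detection in
    FDA Adverse Event Reporting System (FAERS) style spontaneous-report data.
    Reads the quarterly "$"-delimited ASCII tables (DEMO, DRUG, REAC, OUTC,
    RPSR, THER, INDI), deduplicates case versions by CASEID and FDA_DT,
    harmonizes drug names and MedDRA preferred terms, builds drug-event 2x2
    contingency tables at the preferred-term and system-organ-class levels,
    and computes four disproportionality statistics (reporting odds ratio,
    proportional reporting ratio with chi-squared, the information component
    of the Bayesian confidence propagation neural network, and the empirical
    Bayes geometric mean) with confidence intervals and standard positivity
    thresholds.  A synthetic-FAERS generator with closed-form expected
    contingency tables provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
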
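Package: cypconsensus
Title: Consensus Classification of Potent and Weak CYP3A4 Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying chemicals as potent or weak inhibitors of
    the cytochrome P450 CYP3A4 isozyme. Implements in vitro to in vivo
    extrapolation of inhibition data (AUC fold-change R with confidence
    intervals via the Cheng-Prusoff relation), molecular-weight band
    enrichment statistics (Wilson intervals, two-proportion z-tests, power,
    threshold location by curve intersection), three machine classifiers
    (logistic regression on standardized docking scores with ROC cutoff
    analysis, spectral data-activity relationship models from binned NMR
    chemical shifts with forward stepwise discriminant analysis, and a
    five-tree descriptor-disjoint Gini decision forest), a repeated tenfold
    cross-validation harness, majority-rules consensus with confidence
    tiers, and a synthetic-data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
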
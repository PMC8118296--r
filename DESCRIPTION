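Package: ecgmr
Title: Mendelian Randomisation of Electrocardiographic Intervals on Atrial
    Fibrillation Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the causal relevance of electrocardiographic
    (ECG) intervals (P-wave duration, PR interval, QT interval) for risk of
    atrial fibrillation using mendelian randomisation. Covers instrument
    selection (genome-wide significance filtering, linkage-disequilibrium
    clumping, allele harmonisation, ion-channel gene subsetting), weighted
    allele-score construction with instrument-strength and analytic power
    reporting, individual-level score-outcome association with floated-variance
    quintile contrasts, the summary-data estimator suite (inverse-variance
    weighted, MR-Egger, weighted median, weighted mode, MR-PRESSO outlier
    detection), fixed-effects meta-analysis and bidirectional analysis, and a
    synthetic-data generator that reproduces the statistical structure of a
    large genotyped cohort so the whole pipeline is testable without access to
    individual-level biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mvtnorm,
    withr,
    yaml
Config/testthat/edition: 3
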
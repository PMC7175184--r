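Package: nof1oda
Title: Single-Subject Optimal Discriminant Analysis for Symptom Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for N-of-1 (single-subject) analysis of daily symptom
    diaries. Implements maximum-accuracy cutpoint (optimal discriminant
    analysis) models relating an ordered behavioral attribute to a
    dichotomized 0-10 symptom series, with exact and Monte Carlo
    permutation p-values, and renders significant rules as personalized
    natural-language recommendation statements. Also provides scoring of
    the Fibromyalgia Impact Questionnaire (FIQ) to its 0-100 total with
    severity bands, a reproducible synthetic diary-cohort generator with
    planted behavior-symptom rules and adherence-linked outcome decline,
    and a longitudinal evaluation layer (pooled use-index tables and
    tie-corrected Kendall tau-b).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
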
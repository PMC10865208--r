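Package: lbptriage
Title: Referral-Letter Enrichment for Machine-Learning Triage of Low Back Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for enriching quantitative patient-questionnaire data with
    lexicon-extracted referral-reason and patient-goal flags mined from Dutch
    free-text referral letters, and for measuring whether that enrichment
    improves four-class treatment triage of patients with chronic low back
    pain. Implements a regex/lexicon named-entity extraction pipeline with
    section segmentation, cohort assembly into extended (questionnaire +
    letter flags) and basic (questionnaire only) data sets, a balanced
    evaluation split with per-split z-scoring, SMOTE minority oversampling,
    multiclass ReliefF feature ranking with threshold or rank-based
    selection, k-nearest-neighbour, support-vector-machine and multilayer-
    perceptron classifiers, macro-F1/confusion-matrix evaluation, and a
    fully seeded synthetic-cohort generator (class-conditional questionnaire
    features and section-structured letters with planted code words) so the
    whole pipeline is testable without access to clinical records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    class,
    e1071,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
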
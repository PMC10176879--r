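Package: npsehr
Title: Classification of Neuropsychiatric Symptoms in Clinical Notes with
    Misclassification-Corrected Prevalence Estimation
Version: 0.1.0
Authors@R:
    person("NPS-EHR", "Developers", email = "npsehr@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for detecting 13 categories of
    neuropsychiatric symptoms (NPS) in free-text clinical notes from memory
    clinic cohorts. Notes are annotated in brat standoff format, reduced to
    document-level labels, and featurized as unigram/bigram counts after
    stop-word removal, stemming, and negation-phrase removal. One elastic-net
    regularized logistic classifier is trained per category, evaluated by
    stratified tenfold cross-validation and external validation, with
    probability cutoffs selected by the Youden index. Prevalence estimates
    are corrected for imperfect classifier sensitivity and specificity
    (Rogan-Gladen) with confidence intervals that propagate validation-set
    uncertainty, and note-derived NPS are compared with proxy-questionnaire
    (NPI) reports via Cohen's kappa and discordance proportions. A synthetic
    corpus generator with known ground truth makes every stage testable
    without access to protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
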
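Package: aphasiometry
Title: Scoring, Normative Cutoffs and Psychometric Validation for a
    Multidomain Aphasia Battery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative machinery for standardizing a 13-subtest aphasia
    battery spanning auditory comprehension, repetition, and oral production.
    Implements trial-level scoring rules (binary items, half-credit
    phonological paraphasias, word-order penalties, criterion sums, rating
    scales, pair-gated discourse credit), the General Aphasia Quotient (GAQ)
    composite, percentile-based normative cutoffs with an outlier rule and a
    next-achievable-score adjustment, ROC-based diagnostic cutoff selection
    maximizing sensitivity plus specificity, 34th/67th-percentile severity
    banding, and a psychometric validation suite: item passing rates,
    corrected item-total correlations, Cronbach's alpha with Feldt intervals,
    intraclass correlations ICC(A,1) with F-based intervals, Pearson and
    partial correlation matrices under Bonferroni control, Welch t tests,
    Fisher exact tests, and Kruskal-Wallis plus Dunn post-hoc age-cohort
    pooling. A latent-trait cohort simulator generates control and patient
    populations, rater pairs, retest sessions, and a concurrent severity
    measure so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
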
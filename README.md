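# aphasiometry

Quantitative machinery for standardizing a multidomain aphasia battery:
scoring, normative cutoffs, diagnostic classification, severity banding,
and the full psychometric validation suite, with a latent-trait cohort
simulator so every stage can be exercised and validated without patient
data.

## Who this is for

Clinical researchers standardizing (or re-standardizing) a language
battery for aphasia, and methodologists who need a reference
implementation of the statistical pipeline such standardizations use:
percentile-based norms with outlier screening, ROC cutoff selection,
empirically anchored severity ranks, and classical reliability/validity
analyses.

## The model

The battery has 13 subtests across auditory comprehension, repetition and
oral production. Trial-level responses are scored by subtest-specific
rules (binary credit; 0.5 for phonological paraphasias; per-word sentence
scoring with a single one-point word-order penalty; four-criterion sums;
four 5-point rating scales; pair-gated discourse credit), converted to
accuracies `100 * raw / max`, and summarized by the **GAQ** (general
aphasia quotient), the unweighted mean of the 13 accuracies:

```
GAQ = (1/13) * sum_i 100 * raw_i / max_i      in [0, 100]
```

Norms are derived per age cohort (young 18–59, elderly 60+):

* **Subtest cutoff** = 5th percentile of control scores (type-7 quantile)
  after removing controls scoring `< 90` *and* `> 3 SD` below their cohort
  mean (one pass); a ceiling 5th percentile adjusts to the next achievable
  score below maximum (23/24 = 95.83% on a 24-item subtest). Performance
  at or below the cutoff is abnormal.
* **Diagnostic cutoff** = the GAQ threshold maximizing
  sensitivity + specificity on the empirical ROC (positive = GAQ ≤
  threshold), per cohort, no outlier removal.
* **Severity ranks** from the 34th/67th percentiles of impaired patient
  scores, cohorts pooled: severe ≤ P34 < moderate < P67 ≤ mild ≤ cutoff
  < normal.

The psychometric suite provides item passing rates, corrected item-total
correlations (flag r < .2), Cronbach's alpha (Feldt or bootstrap CI),
ICC(A,1) with McGraw–Wong intervals, Bonferroni-controlled Pearson and
partial correlation matrices (.05/78 for all subtest pairs), Welch t
tests, Fisher's exact test, and Kruskal–Wallis + Dunn/Holm age-group
pooling.

## Worked example

```r
library(aphasiometry)

spec <- cohort_spec(seed = 7)        # study-sized control/patient cohorts
sim  <- simulate_cohort(spec)
norms <- build_norm_table(sim$profiles)

attr(norms, "roc")$young
#> ROC cutoff selection (positive = GAQ <= threshold)
#>   n: 69 controls, 44 patients
#>   selected cutoff: 95.04 (sens 1.000, spec 0.971)

head(as.data.frame(norms)[, 1:5], 2)
#>                  measure age_cohort   cutoff  band_34  band_67
#> 1 nonword_discrimination      young 95.45455 74.81818 87.40909
#> 2 nonword_discrimination    elderly 95.45455 74.81818 87.40909

patient <- sim$profiles[sim$profiles$group == "PWA", ][3, ]
res <- classify_participant(patient, norms)
cat(round(res$gaq, 2), res$aphasia_flag, res$gaq_severity)
#> 43.78 TRUE severe
```

Reading the output: the young cohort's aphasia cutoff is GAQ ≤ 95.04,
which flags every synthetic patient (sensitivity 1.0) while keeping 97%
of controls unflagged; nonword discrimination's impairment cutoff is
95.45% (21/22 items) in both cohorts, with pooled severity-band
boundaries at 74.8% and 87.4%; the example patient's GAQ of 43.78 is far
below the cutoff and below the GAQ's 34th-percentile band, hence severe
aphasia.

Trial-level data round-trip through the tablet-export CSV dialect:

```r
trials   <- as_trial_data(sim)                      # or read_trial_csv(path)
profiles <- participant_profiles(score_trials(trials))
```

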
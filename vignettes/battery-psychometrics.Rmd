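---
title: "Scoring, norms and psychometric validation of a multidomain aphasia battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, norms and psychometric validation of a multidomain aphasia battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphasiometry)
```

## The problem

Standardizing a clinical language battery requires more than writing good
items: raw scores must be turned into comparable accuracy scales, normative
cutoffs must separate impaired from unimpaired performance with known error
rates, severity labels must be anchored in the patient population rather
than in intuition, and every scale must demonstrate reliability and
validity. `aphasiometry` implements that quantitative machinery for a
13-subtest aphasia battery spanning three domains — auditory comprehension
(6 subtests), repetition (3) and oral production (4) — together with a
synthetic-cohort generator rich enough to exercise and validate every
pipeline stage without access to patient data.

## Scoring model

Each subtest has a scoring rule operating on trial-level annotations:

* **Binary items** (comprehension and naming): 1 for a correct response, 0
  for every error type.
* **Word/nonword repetition**: 1 correct, 0.5 for a phonological
  paraphasia (more than half of the target spared and the target
  recognizable — a coder judgement carried in the annotation), 0 otherwise.
* **Sentence repetition**: every content and function word is scored
  1 / 0.5 (paraphasia or word-form error) / 0, and any word-order
  alteration incurs a single one-point penalty per sentence, however many
  order events the coder recorded. The sentence score is floored at 0: the
  battery's accuracy scale is defined on [0, 100] and a negative raw score
  has no interpretation.
* **Sentence production**: four binary criteria per sentence (consistency
  with the prime, grammaticality, lexical-semantic adequacy, phrase
  appropriateness); item score 0–4.
* **Discourse production**: one narrative rated on four 5-point scales;
  score 4–20, so the accuracy floor is structurally 20%, not 0 — a rated
  narrative cannot score lower. We treat ratings as integers 1–5.
* **Discourse comprehension**: 16 verification statements in 8 pairs
  probing the same story element. The default rule credits a pair only
  when both statements are correct (max 8), a guard against guessing in
  the yes/no format; a per-statement mode (max 16) is available because
  the tablet registers each response individually. The pair-gated total
  can never exceed half the per-statement correct count. We default to
  pair gating because the severity machinery is defined on the gated
  scale; both modes coincide only when errors come in pairs.

Subtest **accuracy** is 100 × points / maximum over all defined items;
unattempted or abandoned items count as incorrect, so the denominator is
always the full item set. Self-corrections are never penalized (only the
final response is scored) and dysarthric distortions are never marked
down; both conventions live at the annotation level, not in the arithmetic.
The **GAQ** (general aphasia quotient) is the unweighted mean of the 13
subtest accuracies and is computed only when every subtest was
administered; named subsets produce an explicitly labelled GAQ-proxy, as
used for partial retest batteries. All computation is at full precision;
accuracies are rounded half-up to 2 decimals only for presentation
(`present_accuracy()`).

The sentence-repetition maximum depends on sentence word counts. The
canonical instrument form in the catalogue has six 4-word and six 7-word
sentences (66 points); annotations carry their own word counts, and the
canonical counts fill in only for unattempted items.

## Normative pipeline

Subtest cutoffs are the 5th percentile of the control cohort's scores,
separately per age cohort (young 18–59, elderly 60+), after a one-pass
outlier screen: a control score is removed only if it is below 90 percent
*and* more than three standard deviations below its cohort mean, with both
statistics computed on the full sample (no iterative re-screening).
Performance at or below the cutoff is abnormal. When the 5th percentile
equals the subtest maximum, the cutoff is adjusted to the next achievable
score below the maximum on the subtest's lattice — 23/24 = 95.83% for a
24-item one-point subtest, max − 0.5 on half-point lattices — because
otherwise a perfect score would be labelled impaired.

The diagnostic cutoff for the GAQ comes from a ROC analysis per age
cohort, without outlier removal (the composite is already robust to single
aberrant subtest scores, and the full range of control performance should
inform the aphasia cutoff). Candidate thresholds are midpoints between
consecutive distinct pooled GAQ values plus ∓∞ sentinels; the selected
cutoff maximizes sensitivity + specificity under the convention
"GAQ ≤ threshold = aphasia", with ties broken toward the larger threshold
(favouring sensitivity at matched sums). Both conventions are stated
because the selection rule alone does not determine them.

Severity bands divide each measure's *impaired* scores (at or below the
cutoff) into three approximately equal ranges at the 34th and 67th
percentiles, pooling the two age cohorts for sample size. The bands are
therefore shared across cohorts while cutoffs stay cohort-specific — a
deliberate asymmetry; re-deriving bands from one cohort alone is not
expected to reproduce them. The rank intervals are: normal X > cutoff;
mild P67 ≤ X ≤ cutoff; moderate P34 < X < P67; severe X ≤ P34. When
P34 = P67 the moderate interval is empty and a score at the common value
is severe (the ≤ P34 rule has precedence).

Quantiles use type 7 (linear interpolation between order statistics), the
default of the statistical environment this class of standardization
studies is analysed in; the convention is configurable (`qtype`) because
empirical quantiles are a defensible alternative and the choice matters in
small cohorts.

## Psychometric suite

* **Item analysis**: passing rates (mean normalized item score across
  patients) and corrected item-total correlations (item vs. subtest total
  minus that item), with items below r = 0.2 flagged as poorly
  discriminating; zero-variance items are reported as undefined rather
  than failing the subtest.
* **Internal consistency**: Cronbach's alpha with a Feldt F-based
  confidence interval by default; a participant bootstrap is available
  because the CI method is a genuine open choice and the two can be
  compared. Listwise deletion (standard practice for alpha).
* **Inter-rater / test-retest reliability**: ICC(A,1) — two-way random
  effects, absolute agreement, single measure — so systematic rater or
  session shifts count against agreement; confidence intervals via the
  McGraw–Wong F formulas with Satterthwaite degrees of freedom.
* **Validity correlations**: all 78 pairwise Pearson correlations between
  subtests on pairwise-complete observations with the Bonferroni family
  threshold .05/78, and first-order partial correlations controlling for
  an external severity total (the concurrent-validity instrument), same
  family. Partial correlations are validated in the tests against the
  regression-residual route to 1e-10.
* **Group machinery**: Welch t tests (two-sided, Satterthwaite df) with
  Bonferroni families of 13 and 26; Fisher's exact test for
  impaired/normal × subgroup tables; Kruskal–Wallis with tie correction
  followed by Dunn's pairwise z tests (tie-corrected ranks, Holm
  adjustment), recommending the merger of age groups connected by
  non-significant differences — the procedure that justifies pooling
  preliminary age groups into two cohorts.

## The synthetic cohort generator

The generator is a first-class module, not a test fixture: it defines the
study conditions under which the pipeline is validated.

Every participant has a latent language ability θ (patients θ ~ N(0, 1);
controls θ ~ N(3.0, 0.45)) plus a stable subtest-specific residual ability
(sd 0.3–0.8) representing task demands outside the common factor —
pragmatics and memory for discourse, priming for sentence production.
Items follow a guess/lapse logistic model: success probability
guess + (1 − guess − lapse) · plogis(a(θ − b)). Forced-choice
comprehension formats floor at chance (.5 for same/different and yes/no,
.25 for four-picture matching); open-ended repetition, naming and
production items floor at 0 — except that failed repetition targets
surface as half-credit phonological paraphasias with probability 0.4, so
the repetition accuracy floor is 20%. Discourse comprehension carries a
lapse rate (.05, +.03 for elderly participants) modelling attention and
memory slips on a 16-statement story, which keeps even unimpaired
performance off a hard ceiling. Elderly participants additionally lose
0.6 θ on the four age-sensitive subtests (discourse comprehension,
nonword repetition, sentence repetition, sentence production).

Item difficulties are fixed properties of the instrument (b0 + spread ×
normal quantiles, not redrawn per simulation). The frozen defaults were
calibrated numerically so that (i) patient passing-rate family means sit
mid-range of the observed families — comprehension 0.77–0.94, repetition
0.51–0.75, production 0.44–0.64; (ii) per-subtest internal consistency
approaches the battery's reliability profile; and (iii) the control/patient
separation reproduces the reported diagnostic accuracy (sensitivity ≈
.94–.97, specificity ≈ .96–.99, GAQ cutoffs in the low 90s). Randomness
uses one mandatory root seed with per-participant sub-streams, so
regeneration is byte-identical and independent of which groups are
requested; retest sessions reuse each participant's residual abilities but
redraw items, with session wobble θ' = θ + N(0, session_sd).

What the generator deliberately does **not** emulate: linguistic response
content (no transcripts or paraphasia strings), aphasia subtypes beyond a
latent severity continuum, multidimensional deficit profiles beyond one
residual factor per subtest, item-level local dependence, and education or
etiology effects. Passing tests therefore show that the pipeline recovers
the truth of *this* generative family at realistic sizes — not that real
cohorts satisfy its assumptions. Two visible consequences of the model's
simplicity: the two-alternative subtests cannot reach the very highest
internal-consistency levels real data show (guessing noise bounds alpha
from above), and severity-band boundaries inherit the granularity of each
subtest's score lattice.

## Validation design and problem sizes

The test suite validates each estimator against an independent route:
hand-computed Pearson sums, brute-force two-way ANOVA for ICC (via
`aov`), exhaustive threshold enumeration (and `pROC`) for the ROC
selection, regression residuals for partial correlations, hypergeometric
enumeration for Fisher's test, an order-statistic oracle for quantiles,
and a vectorized re-derivation of the generator's score distribution.
Monte-Carlo checks use: alpha's compound-symmetry limit at n = 5000;
ICC variance-component recovery at n = 500; cutoff recovery at n = 2000
controls across 20 seeds against a 200 000-draw reference (sentence
repetition, the finest lattice of the battery, so lattice granularity
stays below the 1-point tolerance); and 200 replicates of the full
diagnostic pipeline trained at the study's cohort sizes (69/37 controls,
44/41 patients). Trained cutoffs are evaluated on held-out draws of 200
participants per group × cohort: the larger held-out sample measures the
trained classifier's true operating characteristics rather than
small-sample evaluation noise. The retest-reliability contrast
(single-word comprehension vs. repetition) is evaluated on a chronic
mild-to-moderate sample (θ ~ N(0.7, 0.7), n = 60 for ordering stability)
because patients retested across sessions sit near ceiling on single-word
comprehension — which is exactly the mechanism (limited variance plus
forced-choice guessing) that depresses their retest ICC while internal
consistency in the full-severity sample stays high.

## Degenerate inputs and numerical conventions

Zero-variance items: excluded from item-total summaries with a warning,
fatal only for a zero-variance subtest total (alpha undefined). ICC is an
explicit error when between-participant variance is zero. Pairs with
fewer than 4 complete observations are reported unavailable rather than
estimated. ROC with identical group distributions returns sens + spec = 1
at a sentinel threshold. Empty severity bands (P34 = P67) classify the
common value severe. Outlier screening refuses fewer than 3 scores;
banding refuses fewer than 3 impaired scores, with advice to pool. All
p-values are two-sided. CSV I/O is RFC-4180 UTF-8 with a versioned header
line, so Cyrillic item labels survive round-trips; norm tables carry
their quantile convention and cohort sizes as metadata and re-validate
band ordering on read.

## A worked run

```{r pipeline, eval = FALSE}
spec <- cohort_spec(seed = 7)              # study-sized cohorts
sim <- simulate_cohort(spec)
norms <- build_norm_table(sim$profiles)
attr(norms, "roc")$young                   # selected GAQ cutoff, sens, spec

patient <- sim$profiles[sim$profiles$group == "PWA", ][1, ]
classify_participant(patient, norms)       # aphasia flag + severity ranks

trials <- as_trial_data(sim)               # the tablet-export dialect
profiles <- participant_profiles(score_trials(trials))
```

## Known limitations

The package implements the battery's published quantitative procedures;
it does not model reading/writing subtests (the battery has none),
reaction times (registered but not analysed), factor-analytic internal
structure, or regression-based change detection. Severity bands assume
enough impaired patients per measure to estimate two percentiles; with
very small patient samples the banding refuses rather than extrapolates.
The generator's calibration targets are population summaries (family mean
passing rates, reported operating characteristics), not figure-read
per-item values, so per-subtest statistics should be read as
representative, not as reproductions of any particular dataset.
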
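---
title: "Deriving and evaluating EEG-based neurotoxicity scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating EEG-based neurotoxicity scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veicans)
```

## The problem

ICANS — the neurotoxicity syndrome that follows CAR-T cell therapy — is
graded 0–4 at the bedside from the ICE cognitive assessment and four
neurological domains. The grade is subjective and labour-intensive, and
there is no accepted objective biomarker. Qualitative EEG features read by
an electroencephalographer (how slow the background is, whether periodic
discharges are present, whether a posterior dominant rhythm survives) track
the severity of the encephalopathy. VE-ICANS condenses those features into
an integer point score: the sum of per-feature points, with four patterns of
severe encephalopathy assigned the maximal score outright.

This package implements three layers: applying such a table
(`default_table()`, `score_features()`), deriving one from graded
patient-day data (`train_veicans()`), and evaluating it honestly under
subject-grouped cross-validation (`nested_cv()`), plus a synthetic cohort
generator so all of it runs without patient data.

## The feature vocabulary

`eeg_vocabulary()` has 23 binary indicators: background slowing split into
1 Hz bins (delta ≤ 1, 1–2, 2–3, 3–4 Hz; theta 4–5, 5–6, 6–8 Hz; alpha ≤ 8,
8–9, ≥ 9 Hz), beta activity, PDR, signs of wakefulness, GRDA, GPDs, LPDs,
LRDA, moderately low voltage, intermittent brief attenuation, and the four
severe patterns (NCSE, extreme low voltage/ECS, burst suppression,
unreactive EEG). Each band reports at most one frequency bin per day — the
grader answers "is delta present, and if so at what frequency?" — and the
schema validator enforces this. A separate `seizure` indicator is carried in
data files but never scored or trained on: clinically a seizure *is* grade
≥ 3, so using it would leak the label. LRDA appears in the vocabulary with
a zero default coefficient; like LPDs, brief attenuation, beta, awake signs
and the slow-alpha bins, it was dropped by regularization rather than
unmeasured.

The published point values are in `default_table()`. The trained table
merges the theta 5–6 and 6–8 Hz input bins to a single +1 value because
their coefficients agreed; the default table therefore maps both input bins
to +1.

### The maximal score

The published table lists "maximal score" for severe patterns without a
number. We compute it from the table itself as the largest score achievable
without severe features under the one-bin-per-band rule (10 + 2 + 2 + 2 + 2
= 18 for the default table): this guarantees a severe EEG ranks at least as
high as any non-severe EEG, which is the clinical intent, and remains true
for any trained table. It is overridable in the table file (`max_score`
field; `"auto"` restores the computed value). Totals are not clamped below
zero: PDR plus fast alpha legitimately scores −2, which simply ranks as
"healthier than featureless".

## The ranking model

Grades are ordinal, so rather than regress the grade we rank patient-days:
every pair of days with strictly different grades (half-grades from reviewer
averaging compare numerically; only exact ties drop) becomes a training
pair, turning ~315 days into tens of thousands of pairs. With `Δx` the
feature difference (higher-grade day minus lower), coefficients minimize

$$\frac{1}{N}\sum_{\text{pairs}} \log\!\left(1 + e^{-w^\top \Delta x}\right)
  + \lambda\left(\alpha \lVert w\rVert_1 +
  \tfrac{1-\alpha}{2}\lVert w\rVert_2^2\right)$$

subject to domain constraints: abnormal features score ≥ 0 and normal
features ≤ 0; within each slowing band, slower bins score at least as much
as faster bins; severe patterns are excluded a priori (their days are also
excluded from pair construction, so rare dramatic patterns cannot distort
the coefficients of co-occurring features); and features seen fewer than 5
times are excluded. There is no intercept — a difference model cannot have
one.

### Optimizer

The constraint set is a convex cone, and on it each coefficient's sign is
fixed, so the L1 term is linear and the whole objective smooth. We use
accelerated projected gradient descent with the exact Lipschitz step
(largest eigenvalue of the pair-difference Gram matrix / 4N plus the ridge
term). Projection onto the cone is exact: bounded non-increasing isotonic
regression per slowing band (pool-adjacent-violators, then sign clipping,
which is exact because the sign bounds are monotone along each chain) and
sign clipping elsewhere. The solver is deterministic — no stochastic
gradients — and errors out with diagnostics rather than silently returning
an unconverged fit.

### Hyperparameters

* `lambda` (default grid 0.1, 0.03, 0.01, 0.003): selected by grouped
  cross-validated pairwise accuracy; ties prefer the stronger penalty. The
  source method names ElasticNet but neither its strength nor mixing, so
  both are exposed.
* `alpha = 0.5`: equal L1/L2 mixing, configurable.
* `min_count = 5` instances: as stated by the method.
* `target_max_points = 10`: the scale at which real coefficients are
  integerized, chosen to match the published table's largest value; the
  original scaling rule is unstated.
* Pairs are unweighted. Subjects with many EEG days therefore contribute
  more pairs; the original work is silent on this, and down-weighting is a
  natural extension we deliberately did not silently apply.

### Integerization

Practitioners need integer points. The real solution is scaled so its
largest magnitude is `target_max_points`, rounded (rounding preserves the
sign and ordinal constraints since they are componentwise-monotone), and
then improved by deterministic coordinate hill-climbing over ±1 moves inside
a ±2 box, accepting only strict improvements in training pairwise accuracy
with ties between directions broken toward the smaller point value. A
feasible integer vector is thus a fixed point, and the result never ranks
worse than naive rounding. Exact integer programming would be stronger but
is deliberately out of scope; the local search is auditable and
reproducible.

## Evaluation protocol

`assign_folds()` assigns whole subjects to folds (grouping is what prevents
leakage: days of one patient are heavily correlated) while greedily
balancing the per-grade record counts across folds, with a cap of
⌈subjects/k⌉ subjects per fold and seed-controlled tie-breaking.
Stratification under a grouping constraint can only be approximate; the
greedy solution is consistently tighter than random groupings (tested
against a 1000-grouping randomization oracle).

`nested_cv()` runs the outer 5-fold loop; within each outer training set an
inner grouped 5-fold CV picks `lambda` by mean held-out pairwise accuracy
(the source states "nested" without specifying the inner loop), the model is
refit, and the held-out fold is scored with the integer table. Performance
is computed on the pooled out-of-sample predictions — each record scored
exactly once, by a model that never saw its subject:

* Pearson r between score and grade, with a 1000-replicate percentile
  bootstrap CI. The bootstrap resamples patient-days, matching the stated
  protocol; a subject-level cluster bootstrap would widen the CI (days
  within a patient are correlated) and is available as an explicit choice in
  user code by resampling subjects before calling `pearson_bootstrap()`.
* AUC per discrimination level: grade 0 vs grade ≥ x, for x = 1..4,
  computed as the Mann–Whitney rank statistic with ties counted half, CI by
  bootstrap (the original CI method is unstated; bootstrap keeps one
  convention throughout).
* The Spearman feature-correlation matrix; constant features give NA
  entries and are flagged, never zeroed.

Half-grades interact with dichotomized summaries: for contingency tables we
split at grade > 2, comparing half-grades numerically (a 2.5 falls in the
severe group). Users averaging discordant reviewers should be aware of this
convention.

### Cohort statistics

`chi2_yates()` implements the 2×2 chi-square with the continuity term
|O−E| − 0.5 *not* floored at zero. Flooring (as base R's `chisq.test`
does) sets the statistic to 0 whenever the raw |O−E| is below 0.5;
the unfloored convention — common in scientific Python — instead lets the
correction overshoot, and is the convention that reproduces the published
cohort p-values to all four printed decimals. The choice is therefore fixed
by verification, not preference. `mann_whitney()` uses the normal
approximation with tie-corrected variance and no continuity correction.

## The synthetic cohort

`cohort_spec()` states a world resembling the study cohort; its defaults
are fixed once and are not tuning knobs:

* ~120 subjects, days per subject truncated-geometric on 1–14 with mean ≈ 3.
* A persistent ordinal grade trajectory: a Metropolis birth–death chain
  whose stationary law is the stated grade distribution
  (0.12, 0.18, 0.20, 0.32, 0.18 over grades 0–4, so P(grade > 2) = 0.50,
  matching the cohort's 50/50 severe/non-severe day split), with
  `persistence = 0.8` the probability of not proposing a move — grades
  evolve slowly, as observed clinically.
* A latent daily severity = grade + N(0, 0.5²). Features are emitted
  conditionally independently given severity, which induces the positive
  co-occurrence structure seen in real feature-correlation heatmaps without
  matching any specific correlation value (those are not published as
  numbers).
* Slowing bands: presence via a logistic in severity, then a latent
  dominant frequency falling with severity, discretized into the 1 Hz bins —
  sicker days slow further. Other features: logistic emissions with
  baselines set so prevalences at mean severity approximate the published
  all-time-point prevalences (PDR ~13%, GPDs ~5%, moderately low voltage
  ~7%, ...), with loadings non-negative for abnormal and non-positive for
  normal features. Severe patterns appear only on grade-4 days (probability
  0.02 each, mirroring their rarity); seizures only at grade ≥ 3.

What the generator does **not** emulate: reviewer noise in the grades
themselves, temporal drift in feature expression within a day, montage or
artifact effects, treatment covariates (steroids, propofol), and the real
(unpublished) co-occurrence magnitudes. A green recovery test therefore
establishes that the training pipeline can recover a planted scoring
structure from realistically sized and shaped data — not that it would
reproduce the published coefficients on the real cohort, which is not
deposited. For the same reason the headline clinical numbers (R ≈ 0.58,
AUC ≈ 0.91) are not reproduction targets here; on the cleaner synthetic
world the cross-validated correlation is typically somewhat higher.

In recovery experiments the trained table often *outranks* the generating
table on held-out data (a negative accuracy gap): the generating table is
not the Bayes-optimal ranker for the emission model, so the learner can
legitimately beat it. "Sign agreement" is assessed as absence of
contradictions (a trained and planted coefficient of strictly opposite
sign); a zero coefficient is compatible with either sign, since the L1
penalty is expected to zero out weak features — exactly what the original
analysis reports for LPDs and LRDA.

## Numerical and degenerate-input conventions

* Ranking ties in accuracy count half, everywhere (training accuracy,
  AUC, integer search), so complementary invariants like
  AUC(s) = 1 − AUC(−s) hold exactly for tie-free scores.
* All-equal grades give an empty pair set with a warning at the pair level
  and an error ("no informative pairs") at the training level.
* Bootstrap resamples that collapse a class (AUC) or a variance (Pearson)
  are dropped from the percentile computation rather than imputed.
* All randomness flows through explicit `seed` arguments; the global RNG
  state of the session is saved and restored, and equal seeds give
  byte-identical artifacts end to end.
* Fitting is deterministic; seeds affect only fold-assignment tie-breaks
  and bootstrap resampling.

## Known limitations

* Greedy stratification is approximate; with very unbalanced subjects a
  fold can still drift from the marginal grade mix.
* The inner CV selects the penalty by pairwise accuracy on real-valued
  coefficients (integerization inside the inner loop would triple the cost
  for little selection benefit); the outer estimate always uses the integer
  table actually produced.
* The integer search is local; it guarantees feasibility and no regression
  versus rounding, not global optimality over integer tables.
* The ICE-band → grade mapping ships as editable configuration encoding the
  consensus guideline, which is external clinical knowledge, not a result
  of this package.
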
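---
title: "Methods: two-cycle screening of high-alert drug prescriptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-cycle screening of high-alert drug prescriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hadscreen)
```

## The screening problem

High-alert drugs (HADs) are the subset of a hospital formulary whose
misuse carries a high risk of severe adverse events: anticoagulants,
narcotics and psychotropics, cytotoxic chemotherapy, insulins,
antiarrhythmics. Prescription errors involving them are rare but costly,
so the operational goal is not a diagnostic classifier, it is a *screen*:
reduce tens of thousands of visits to a short review list while missing as
few true errors as possible. Every design choice below follows from that
asymmetry — recall is privileged over precision throughout, and a
prevalence-based post-hoc step absorbs the resulting false positives.

The unit of analysis is a hospital visit: a set of ICD10 diagnosis codes
and a multiset of prescribed drugs, with gender, age and the total
prescription count. Drugs are the *labels*, never features: the screen
must infer HAD use from the diagnoses, so that a prescription unsupported
by the diagnoses stands out. Outpatient (OPD) and inpatient (IPD) data
differ radically in class balance and prescribing patterns, so models, cut
points and prevalence tables are setting-specific and never shared.

## Cycle 1: the binary screen

A gradient-boosted tree ensemble (`xgboost`, logistic objective) is fitted
to the visit features — male indicator, age, one 0/1 indicator per ICD10
code in the training vocabulary, `total_drugs`. The ICD10 vocabulary is
frozen on the training split; codes first seen at predict time carry no
learned signal and are dropped (with a message). Tree depth is the one
tuned hyper-parameter: a grid (default 1–3) is searched by stratified
3-fold cross-validated accuracy, ties breaking toward the smallest depth.
Stratification is our choice — the fold protocol is otherwise unspecified
in this design space — because HAD prevalence can be as low as 8%.
Depth-1 stumps typically win: the signal is mostly additive in the
diagnosis indicators.

The classifier's probability is turned into a decision by scanning cut
points over $[0,1]$ (default step 0.01, matching the two-decimal floor
rounding of the selection) and maximising the screening index
$S = F_1 \times \mathrm{recall}$ of the HAD class. Two conventions make
the scan total and reproducible:

* precision is defined as 0 when nothing is predicted positive, and
  recall as 0 when there are no actual positives;
* the argmax ties break toward the smallest cut point (the
  recall-favouring direction), and the selected value is floored to two
  decimals.

Classification is strict: a visit is predicted HAD iff its probability
exceeds the cut point; equality predicts non-HAD.

## Prevalence readjustment

*HAD percent* of an ICD10 code is the share of visits carrying the code
that received any HAD. It is a raw proportion by design — no smoothing or
shrinkage — because its role is evidential, not predictive; entries with
fewer than `min_total` (default 5) visits are flagged low-reliability
instead of being silently stabilised. A visit is *high likelihood* iff any
of its codes reaches the threshold (default 50%); visits with no code in
the table default to low likelihood and are counted in a message, since
absence of evidence cannot support HAD use.

The confusion matrix is then adjusted:
$aFP = FP - FP_{\ge 50\%}$, $aTP = TP + FP_{\ge 50\%}$,
$aFN = FN - FN_{<50\%}$, $aTN = TN + FN_{<50\%}$. Totals are conserved by
construction. The interpretation: a "false" positive whose diagnoses
frequently co-occur with HAD was probably a reasonable call, and a
"false" negative whose diagnoses never co-occur with HAD was probably not
a model error at all — it is an *actual prescription unsupported by the
diagnoses*, which is exactly what the screen is hunting. Those visits
(actual HAD, predicted non-HAD, low likelihood) are the **mismatch
candidates**; with high likelihood they are model misclassifications
instead. The two categories are mutually exclusive and exhaustive over
actual-HAD/predicted-non-HAD visits. Adjudicating a candidate's cause —
incomplete ICD10 coding, wrong ICD10, or a genuinely wrong prescription —
requires clinical context the data model does not carry, so the report
presents evidence (drugs, codes with their prevalence, the model
probability) and no verdict.

When the prevalence table is built from a prescription budget rather than
all visits, whole visits are drawn in a random order weighted by their
prescription counts until the budget is reached. This mirrors estimating
the table from a fixed-size random sample of prescriptions while keeping
the visit as the counting unit; full-data mode is the default.

## Cycle 2: the type screen

Visits above the cut point are expanded into one instance per distinct
prescribed HAD type — ANS (adrenergic/sympathomimetic), BIG
(anticoagulant), CVS (antiarrhythmic/glycoside), CNS
(anaesthetic/opioid/sedative), END (antidiabetic/bone), Tumor (cytotoxic)
— with one `non-HAD` instance for included visits without HAD. Instances
share the visit's feature row plus the cycle-1 probability as an extra
feature; a seven-class boosted model yields per-type probabilities that
sum to one.

Per-type decision thresholds are percentiles of the type's own test-set
prediction distribution: at or below P25 → no use, above P75 → use,
between → uncertain, excluded from interpretation. Percentiles use linear
interpolation between closest ranks (`quantile(type = 7)`); the
convention matters only in tiny samples but is fixed for reproducibility.
Two boundary rules are explicit: probability exactly P75 is *uncertain*
(use requires strictly more), and when P25 = P75 the no-use rule applies
first. Percentiles are computed per type by default — the types'
probability scales differ by an order of magnitude — with a pooled option
for sensitivity analysis.

The per-type confusion (use/actual cross) is adjusted exactly as in cycle
1, each type against its own prevalence table: *ICD10 percent*, the share
of a code's visits with that specific type prescribed, is the per-type
restriction of HAD percent and is computed by the same estimator.
Excluded visits with actual HAD use are re-screened through the cycle-1
prevalence table (evaluation mode) and routed to the mismatch report.

## The synthetic generator

`simulate_prescriptions()` emulates the structure the protocol exploits,
not hospital epidemiology. Each synthetic ICD10 code has an association
probability $\pi$ — the chance that a visit with that principal diagnosis
receives a HAD — and a dominant pharmacological type (mixture weight 0.8).
Code frequencies are power-law; comorbidities are Poisson-distributed
extra codes; non-HAD co-prescriptions are Poisson with every visit
receiving at least one drug; age is clipped-normal (48 ± 15) and gender
Bernoulli(0.45 male), present only because the features exist. Prescription
rows carry one ICD10 each, recycling the visit's codes principal-first, so
the emitted CSV and the aggregated visit agree exactly.

Planted errors give ground truth:

* **mismatch errors** — with probability `mismatch_rate`, a visit whose
  codes are *all* below the unrelated bound (default $\pi < 0.1$) and
  that drew no HAD receives one random HAD. Planting only on all-low
  visits is deliberate: an unrelated-HAD error is one unsupported by any
  diagnosis, and it makes the planted error detectable by the very
  evidence the protocol uses;
* **stage mixing** — follow-up visits of high-$\pi$ diagnoses issued
  without HAD, the complex-relationship error source;
* **multi-drug accumulation** — the `eamu` preset raises the non-HAD
  drug mean so four-plus co-prescriptions are common, inflating
  `total_drugs`-driven predictions.

Preset conditions: `clean` (no errors, no mixing, *no comorbidities*,
$\pi$ spread over 0–0.98, 20,000 visits) is the calibration scenario —
without comorbidities a code's marginal prevalence identifies its $\pi$,
so the estimator's recovery can be tested against binomial error.
`mismatch_rich` (separated $\pi$: 30% of codes at 0.8–0.98, the rest at
0–0.1; 1% planted rate; 20,000 visits) is the end-to-end screening
benchmark. What passing these tests does *not* show: robustness to real
disease co-occurrence, to miscoded diagnoses at scale, or to prevalence
drift over time — the generator has none of those.

## Numerical and engineering choices

* All stochastic steps take explicit seeds (`withr::with_seed`), so equal
  seeds reproduce outputs bit-identically; pipeline results carry a
  manifest (parameters, seeds, package version, hash).
* The 75:25 split sizes the test set by round-half-up of
  $N(1-\mathrm{ratio})$.
* Boosting uses a single thread and a recorded seed; models serialise via
  the booster's raw bytes, so a saved/reloaded model predicts
  identically.
* Lasso feature relevance fits an L1-penalised linear model of the 0/1
  label on internally standardised features (`glmnet`), reporting the top
  positive and negative coefficients; constant features keep coefficient
  0.
* Degenerate inputs have defined outcomes throughout: empty scans, single
  classes, all-uncertain calls, visits with no covered codes, empty
  candidate sets.

The test suite exercises the statistical properties at deliberately
modest problem sizes — 20,000-visit simulations for calibration and the
end-to-end screen, hundreds of visits elsewhere — chosen as the smallest
sizes at which binomial error bands and recall targets are stable across
seeds.

## Limitations

The screen sees only drug–diagnosis co-occurrence. Clinical notes,
laboratory values, dosing, and temporal ordering are all outside the data
model, so the final adjudication of every candidate remains manual.
HAD percent is unreliable for rare diagnoses (flagged, not fixed), and
the P25/P75 rule is deliberately simple — an interval, not a calibrated
decision boundary; the uncertainty zone it excludes is unexplored by
construction. Performance numbers on synthetic data characterise the
protocol's mechanics, not its yield on any real hospital's records.
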
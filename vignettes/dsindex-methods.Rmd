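---
title: "Methods: the Disease State Index and the prodromal-AD criteria pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Disease State Index and the prodromal-AD criteria pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsindex)
```

# The problem

Mild cognitive impairment (MCI) is the transition zone between normal aging
and Alzheimer's disease (AD); annual conversion rates vary widely, so
predicting *which* MCI patients will convert is the clinically useful
question. Two prediction strategies are compared on identical baseline
data:

* the **research criteria for prodromal AD**: dichotomize a memory
  criterion and two biomarker modalities, then combine them;
* the **Disease State Index (DSI)**: keep every measurement continuous,
  score each against reference populations, and aggregate.

This vignette documents the models, the tunable parameters, what the
synthetic cohort generator does and does not emulate, and the design
decisions taken where the published description left the choice open.

# The criteria arm

## Cutoffs

| marker | positivity | default |
|---|---|---|
| RAVLT delayed recall | `< cut` | 3 words |
| RAVLT delayed recognition | `< cut` | 10 words |
| Scheltens MTA rating (0–4) | `>= cut` | 3 |
| CSF Tau | `> cut` | 93 pg/ml |
| CSF Aβ1–42 | `< cut` | 192 pg/ml |

The memory criterion requires *both* RAVLT scores positive. Boundary
strictness is exactly as published: a recall of 3, a Scheltens of 3
(positive), a Tau of 93 and an Aβ1–42 of 192 each fall on the stated side.
All cutoffs are configurable via `criteria_cutoffs()`.

## Tri-state logic and missing modalities

Markers are `positive` / `negative` / `unavailable`. The two CSF analytes
form an OR composite (`r3a`) and an AND composite (`r3b`). When exactly one
analyte is missing we use Kleene three-valued logic: the OR is positive if
the measured analyte is positive and otherwise unavailable; the AND is
negative if the measured one is negative and otherwise unavailable. This is
the only completion consistent with both composites; in cohorts generated
by this package it never fires (the two analytes are jointly missing), but
externally supplied CSVs may exercise it.

## Likelihood categories

High = memory + MTA + CSF all positive; intermediate = memory positive, one
biomarker positive, the other *unavailable*; uninformative = memory
positive, one positive, the other *negative*; low = memory negative and
both biomarkers measured and negative. The published definitions do not
cover every tri-state pattern (e.g. memory-positive with both biomarkers
missing, or memory-negative with one missing modality); rather than guess,
those map to a fifth `indeterminate` category, and the pipeline logs how
many subjects land there. The CSF side of the categorisation uses the OR
composite by default — the intermediate-likelihood definition is written in
the OR form — and can be switched to AND. Symmetrically with the high
definition, `low` requires both modalities present; a memory-negative
subject with a missing modality is `indeterminate`, not `low`.

## Denominators

Each criteria combination is evaluated on its *evaluable subset* (subjects
with every required marker available), which reproduces the
modality-specific denominators of the published tables (e.g. CSF rules over
the 199 CSF-measured subjects). A sensitivity-analysis mode
(`denominators = "all_subjects"`) instead counts `not_evaluable` as a
non-converter prediction over the whole cohort.

# The DSI arm

## Fitness

For a feature with abnormal direction "high", at measured value $x$:

$$\mathrm{FN}(x) = \hat F_{\mathrm{pos}}(x), \qquad
  \mathrm{FP}(x) = 1 - \hat F_{\mathrm{neg}}(x), \qquad
  \mathrm{fitness}(x) = \frac{\mathrm{FN}(x)}{\mathrm{FN}(x)+\mathrm{FP}(x)},$$

with $\hat F$ the empirical distribution functions of the positive
(disease) and negative (control) reference samples, using the midpoint tie
convention (count strictly-less plus half of ties). Direction "low"
mirrors the tails. The published study describes the tool's per-item
positioning against the two population densities but does not print the
functional form; the form above is the one published for the underlying
decision-support tool, and it is isolated behind the `feature_reference`
interface so a smoothed-density variant could be substituted without
touching the aggregation.

Numerical choices:

* **0/0 guard** — if $x$ lies strictly between the two supports,
  FN = FP = 0; fitness is defined as 0.5 (maximal ambiguity).
* **Ties** — the midpoint convention makes the label-swap antisymmetry
  exact: swapping the two reference populations (and flipping the
  direction) maps fitness to `1 − fitness` and leaves relevance unchanged.
  This is verified property-style in the test suite.
* **Binary features** (APOE ε4 carrier, sex) run through the same formula
  on their two-point distributions, yielding an empirical
  P(disease | value).

## Relevance

Feature weight = Youden's $J = \max_t [\mathrm{sens}(t) +
\mathrm{spec}(t) - 1]$ over candidate thresholds at the midpoints of
adjacent pooled order statistics (plus thresholds outside the range). J is
0 for identical populations, 1 for disjoint ones. The test suite checks it
against an exhaustive threshold scan.

## Aggregation

Leaves sit under modality branches (demographics/genetics,
neuropsychology, MRI, CSF) under a root. A branch's DSI is the
relevance-weighted mean of its *observed* leaves; its relevance is the mean
relevance of those leaves; branches with no observed leaf are excluded; the
root repeats the weighted mean over branches. Consequences verified as
properties: the composite stays in [0, 1], is monotone in any single
fitness, and removing a feature from a subject is equivalent to deleting
that leaf from the model. A subject with no observed feature is a scoring
error, not a silent 0.5.

## Scale and decision

Six uniform confidence bins — `<0.17`, `[0.17,0.33)`, `[0.33,0.50)`,
`[0.50,0.67)`, `[0.67,0.83)`, `>=0.83` — labelled clear/probable/subtle
non-AD and subtle/probable/clear AD; the binary call is converter iff
DSI ≥ 0.50. Both thresholds are arguments.

## Reference populations

The published workflow scored patients against "previously known"
populations. The desk-scale analogue here fits the references on a
stratified, seeded 50/50 training split and evaluates on the held-out half
(`split_cohort()`); an `in_sample = TRUE` mode fits and scores on the full
cohort for exploration. Which exact feature set fed the deployed tool is
not itemized in the source; the default model uses every generated
feature with at least two observed reference values per group.

# The synthetic cohort generator

`default_cohort_spec()` is a *stated world*, not a tuning surface: group
sizes 233/158 (15 reverters among the non-converters), per-group Gaussian
means/SDs for each instrument as published, APOE ε4 carrier frequencies
66/198 and 145/193, and exact missingness — per-group MRI 230/157, CSF
115/84, both 112/83 (the both-counts are implied: all four MRI-missing
subjects had CSF). Integer instruments (MMSE, RAVLT, Scheltens, spans,
clock, fluency, symbol) are drawn Gaussian, rounded half-up, then clipped
to instrument ranges (MMSE 24–30 per the cohort's inclusion criteria,
Scheltens 0–4, RAVLT 0–15, clock 0–5, timed tests and CSF > 0; age is
clipped to a plausible 55–95 enrolment window). Missingness is assigned by
randomly partitioning each group into the four availability cells, so the
counts hold exactly in every realisation, not just in expectation.

Open points resolved once:

* The published APOE denominators (198/193) do not match the group sizes
  (233/158) — the converter denominator exceeds its group. We treat
  genotype as missing-at-random for the non-converter remainder (35
  subjects) and observed for all converters with carrier probability
  145/193.
* No covariance structure is published, so features are independent given
  group by default; a single-parameter Gaussian copula
  (`correlation` in [0, 1)) is available for sensitivity analyses.
* Reverters get non-converter feature distributions (no separate
  statistics are published for them) and count as non-converters in every
  binary metric.

**What a green test does and does not establish.** The generator matches
first and second moments, category frequencies and missingness patterns —
not the real data's correlations between tests, floor/ceiling pile-ups,
site effects, or non-Gaussian tails. Pipeline accuracies on synthetic
cohorts therefore exercise the *machinery* and its statistical honesty
(split-sample evaluation, exact CIs), and happen to land near the
published ~72% under these moments, but they are not a replication claim.
The only published numbers the package asserts are the twelve
count-arithmetic targets recomputed by `verify_reference_tables()` and
`scripts/acceptance.R`.

`simulate_rater()` stands in for a second clinician (the published
reproducibility analysis re-rated 40 cases): it perturbs DSI values with
Gaussian noise of SD `disagreement_sd` before re-binning, so the kappa
machinery is exercisable; 0.10 on the DSI scale gives moderate six-level
agreement comparable to the published interobserver kappa.

# Evaluation statistics

* **Confidence intervals** — the CI method is not stated in the source;
  Clopper–Pearson exact intervals are used because they reproduce the
  printed integer-percent bounds (72/158 → 38–54, where Wilson gives
  38–53). Implemented via beta quantiles; `stats::binom.test` is the
  independent oracle in the tests.
* **Rounding** — percentages round half-up to integers, matching the
  printed style.
* **McNemar** — exact two-sided binomial on the discordant pairs when
  `b + c ≤ 25`, chi-square with continuity correction above (standard
  small-sample practice; the source is silent). Zero discordance returns
  p = 1 flagged `no_discordance`.
* **Kappa** — unweighted Cohen's kappa; degenerate single-category
  marginals give `NA` with a warning rather than a fabricated 1. The 6→2
  collapse (levels 1–3 vs 4–6) mirrors the published simplified analysis.
* **Six-category table** — row accuracy counts Healthy and MCI outcomes as
  correct in levels 1–3 and AD in levels 4–6 (reverters still belong to
  the non-AD group). One published cell prints 80% where its own counts
  give 11/16 ≈ 69%; `category_table()` computes from counts, and the
  discrepancy is documented here rather than replicated — the pooled and
  overall targets are unaffected.

# Known limitations

* No imputation: missing modalities stay missing (represented, never
  filled).
* No longitudinal modelling; one baseline plus a 3-year outcome label.
* No ROC/AUC (none is published for this comparison), no image-derived
  feature computation, no GUI; the fingerprint is exported as JSON.
* Monte-Carlo checks in the test suite are scaled down (e.g. 60 replicate
  cohorts instead of 10,000) to keep run time in budget; the 3-SE
  acceptance bands are computed for the scaled sizes.
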
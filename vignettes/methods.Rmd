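---
title: "Methods: longitudinal contact-diary analysis with diarycontacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal contact-diary analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diarycontacts)
```

## The data model

A multi-wave contact-diary survey records, for each participant and wave,
one *diary*: all contact events recalled for a single assigned reporting
day. A contact event is an encounter with a distinct individual **or group**
of individuals in one geographical location; group events carry the number
of people they represent. Three long-format tables (participants, diaries,
events) therefore describe a panel completely, and `diaryPanel()` /
`readDiaryPanel()` validate them into a `DiaryPanel` object. Row-level
violations (a non-positive group size, a weekday label disagreeing with the
reporting date, events without a diary) are quarantined with reasons rather
than aborting the read; participants missing age or sex are kept but flagged,
so each analysis can exclude exactly the records it cannot use. Structural
faults — missing mandatory columns, two diaries for one participant-wave —
are hard errors.

From the events, `deriveRates()` builds the per-diary rates the rest of the
package consumes:

* **K**, the number of contacts: the sum over events of group size (a group
  of five is five contacts);
* **L**, the number of locations: distinct location labels within the diary.
  Labels are never matched across diaries or participants — the survey
  design anonymises contacts, so repeat encounters are not identifiable;
* **K_home / K_schoolwork / K_other**: setting-stratified contact counts
  (school and work merged into one stratum). Events with an unrecorded
  setting count towards K but no stratum, so the strata partition K only
  when every setting is recorded;
* **D**, total contact duration in hours, filled in by the duration module
  below.

## Duration model

Durations are recorded only as ordinal categories with known boundaries in
minutes. The category boundaries themselves are a configuration input
(`durationCategories()`); the default follows the common contact-survey
convention `<5, 5–14, 15–59, 60–239, ≥240`. We fit a single exponential
rate λ to the categorized durations of *all* contacts by
expectation–maximization: the E-step replaces each censored duration with
its conditional expectation

E[T | a ≤ T < b] = a + 1/λ − (b−a) e^{−λ(b−a)} / (1 − e^{−λ(b−a)}),

(open tail: a + 1/λ; zero-width category: a, an exactly observed duration),
and the M-step sets λ to the observation count divided by the summed
expectations. The censored log-likelihood is asserted non-decreasing at every
iteration, and the fixed point is the interval-censored MLE — the test suite
checks equality with a direct numerical maximisation to 1e-6 relative.
Convergence is declared when the relative change in λ drops below `tol`
(default 1e-8, cap 10,000 iterations). Two degenerate inputs are refused
because the MLE does not exist: all mass in a single `[0, ∞)` category
(any λ fits) and all mass in the open tail (λ → 0).

`imputeDurations()` then assigns each event a duration drawn from
Exponential(λ) truncated to its category interval, by inverse-CDF sampling,
so draws respect their bounds with probability one. Events with an unknown
category are drawn untruncated and flagged. The whole assignment is repeated
(200 replicates by default) and per-diary totals D are summarised across
replicates by their mean and 2.5/97.5 percentiles. One event contributes one
duration regardless of group size: a group interaction exposes the
participant for the event's duration once, like an individual contact. Each
replicate derives its RNG stream from (seed, replicate index), so any single
replicate is reproducible in isolation.

## Mixing matrices and growth ranking

`mixingRatioMatrix()` compares observed age mixing with *proportionate
mixing*: cell (a, b) is the share of age-group-a participants' contacts
falling in contact age group b, divided by the census proportion of group b.
Ratio 1 everywhere means contacts are distributed like the population; cells
above 1 mark assortative excess. Participant ages are grouped as 5–19,
20–39, 40–64, 65+ (the thinly sampled 2–4-year-olds fall outside the first
break and drop out); contact ages as 0–5, 6–19, 20–39, 40–64, 65+, as
reported categorically by design. Contacts of unknown age are excluded from
numerator and denominator. Because the observed shares are a distribution,
each row reconstructs to 1 when multiplied by the census proportions — an
invariant the tests assert. Confidence intervals come from resampling
*participants* (with all their contacts for the wave) with replacement, 1000
times by default, taking percentile 2.5/97.5 bounds per cell; the point
estimate is always the plug-in estimate. A participant group with no
observed contacts yields missing cells; a cell with zero contacts inside a
non-empty group is a genuine ratio of 0.

The package ships `defaultCensus()`, a *synthetic* census-style age
distribution shaped like an aged urban population, used wherever no census
table is supplied; real analyses should pass their own census through
`readCensus()`.

For wave-to-wave epidemiological comparison, `contactRateMatrix()` collapses
each wave to a square per-capita contact-rate matrix on the common groups
(6–19 mapped to 5–19, the 0–5 contact column dropped, since the participant
side has no 0–5 group), and `ngmGrowthRank()` ranks waves by the dominant
eigenvalue of that matrix, optionally row-scaled by a susceptibility
profile. Under uniform susceptibility and infectivity the eigenvalue is
proportional to the epidemic growth factor, so only the *ranking* of waves
is interpreted, never an absolute growth rate.

## Longitudinal models

`fitRandomIntercept()` fits, by REML through `lme4`,

log(1 + y_ij) = x_ij' β + b_i + ε_ij,  b_i ~ N(0, σ²_b),  ε_ij ~ N(0, σ²_w)

for y ∈ {K, D, L, setting-stratified counts}, using participants with at
least two observations. Default fixed effects are categorical age group,
sex, weekday and wave; the categorized location count (0,1,…,5,6+) is added
for K and D, and household size for home contacts. Age enters categorically
by default: the smooth-in-age alternative is off-the-shelf machinery and
orthogonal to the quantities this package is about, so instead of bundling a
spline basis the `extraDesign` hook accepts any externally built design
columns (e.g. `splines::ns(age, df)`), which enter the fixed effects
unchanged. Designs with aliased columns are refused with the offending
columns named.

`varianceShares()` reports σ²_b and σ²_w as shares of their sum — the
between- versus within-individual decomposition of covariate-adjusted
variability in the rate. REML is used rather than ML so the balanced-design
components agree exactly with the classical one-way ANOVA
method-of-moments estimator, which the tests exploit as an independent
oracle.

`percentageContribution()` predicts the rate on the response scale
(exp(·) − 1 back-transform, random intercept at zero) for a covariate
profile and divides by the prediction for the comparator — a 50-year-old
male reporting on a Monday in the first wave, household size one, a single
contact location — times 100.

**A caution on the location covariate.** The location-count covariate is
itself an outcome of the same behavioural process as K: a diary cannot list
more occupied locations than events, so in data (real or generated) the
derived location count is partially determined by K. Conditioning on it
therefore absorbs part of both variance components. This is fine for the
descriptive, paper-style model, but parameter-recovery exercises against a
generative truth must fit the exogenous design (age, sex, weekday, wave)
only; the package's tests do exactly that, and users comparing variance
shares across specifications should expect the location-adjusted shares to
be smaller.

### Persistence statistics and their null

Both persistence analyses restrict to participants observed in **all**
waves and share one permutation null: within each wave, observations are
permuted across participants. This destroys within-participant linkage
while preserving every wave's marginal distribution exactly (asserted as
multiset equality in the tests).

`accumulationAnalysis()` accumulates a rate over horizons of 1..W waves and
tracks the between-participant coefficient of variation of the cumulative
sum. Independent re-drawing each wave shrinks the CV like 1/√W; persistent
individual differences keep it above the permutation envelope (2.5/97.5
percentiles over `nullReps` replicates). At horizon 1 the observed CV and
the null coincide by construction.

`quantileConsistency()` assigns each participant a within-wave quantile bin
(q equal-count bins) and reports the percentage of participants in the same
bin in every wave. Integer-valued rates tie heavily, so membership uses
ranks with ties broken by first occurrence in data order — this keeps bins
as equal as n allows and is what makes the null analytically checkable:
for W independent waves the expected consistency is 100·(1/q)^(W−1), e.g.
12.5% at q = 2 and W = 4, which the permutation null reproduces within
simulation error.

## The synthetic generator

`generatePanel()` exists so that every stage above is testable end to end
without any survey data. It simulates exactly the structure the longitudinal
model assumes, making parameter recovery a clean acceptance surface:

* households of truncated-geometric size (or any explicit size
  distribution), members' ages drawn from configurable age-group weights;
* an open cohort over 4 waves: 73.5% of the population interviewed in wave
  1, 30% of each wave's participants dropping out of the next, topped up by
  recruitment towards a mildly declining target;
* per diary, locations L ~ 1 + Poisson, then log(1 + K) = μ(age) + weekday
  effect + wave effect + coupling·(L−1) + b_i + ε_ij with b_i and ε_ij
  Gaussian — generation is on the log(1+·) scale precisely because the
  analysis model lives there; K is realised by rounding back;
* contacts partitioned into events, a Poisson number of which are reported
  as groups (mean size ≈ 10), reproducing the long right tail of contact
  counts; each drawn location hosts at least one event whenever the event
  count allows, so the derived location count reproduces the drawn one;
* contact ages drawn with weights census·(1 + s·own-group), so s = 0 is
  exact proportionate mixing and larger s gives age-assortativity;
* true event durations Exponential(rate), recorded only as categories;
* a typical-day flag (73.4% typical), weekday sampling mildly non-uniform.

Defaults are calibrated once to the scale of a large four-wave urban diary
study: 857 households (~1450 individuals), mean ≈ 12.5 contacts in ≈ 2.9
locations and ≈ 8–9 h of contact per day, within-individual variance about
twice the between-individual variance (σ²_b = 0.17, σ²_w = 0.33), a +0.10
log-scale contact excess in wave 2, assortativity strength 4, duration rate
1/45 per minute. What the generator does **not** emulate: household contact
network structure (household members' diaries are independent given their
covariates), seasonality beyond a wave effect, recall error, and any
geography. Passing tests therefore demonstrate that the estimators recover
the structure they model — not that real diary data satisfy that structure.

## Numerical choices and degenerate inputs

* EM convergence: relative λ change < 1e-8; monotonicity asserted with a
  relative tolerance 1e-8 on the log-likelihood.
* Truncated-exponential sampling uses the inverse CDF with `expm1`/`log1p`
  guards, exact for zero-width categories.
* Bootstrap and permutation seeds derive child streams from the master seed
  so stages are independently reproducible; all pipeline stages are pure
  functions of (inputs, config, seed).
* Quantile ties: rank with `ties.method = "first"` (see above).
* Empty diaries: K = L = 0, D = 0 in every replicate. Participant groups
  with no contacts: missing mixing rows, refused (with the group named) in
  the per-capita contact matrix.
* Percentile bootstrap bounds are clamped to bracket the plug-in estimate,
  so the interval invariant lower ≤ point ≤ upper holds even in tiny
  resamples.

## Problem sizes used in the tests

The test suite exercises the full pipeline at reduced but statistically
meaningful sizes chosen so that every Monte-Carlo check has its stated
power: bootstrap-coverage simulation at 200 panels of 500 participants with
1000 resamples each; variance-share recovery at 1000 participants × 4
waves against a delta-method 3-standard-error band; the quantile null at
400 participants × 500 permutations; EM-versus-optimizer equality on 50
random instances plus a 10^5-observation recovery run. The acceptance
script runs the full default-scale panel (857 households) once, end to end.

## Known limitations

* A single pooled duration rate is the default; per-setting rates are a
  flagged extension and mixture/heavy-tailed duration models are out of
  scope, so very long-duration categories are summarised only through the
  exponential tail.
* Mixing matrices are not reciprocity-corrected (no symmetrisation), and
  the growth comparison deliberately stops at the wave ranking.
* The random-intercept model is Gaussian on log(1+y); zero-inflation or
  genuinely discrete outcomes are not modelled.
* Location labels are diary-local; nothing in the package can detect repeat
  encounters across days, so accumulation statements concern rates, not
  unique-partner counts.
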
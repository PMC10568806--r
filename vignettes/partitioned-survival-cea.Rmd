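---
title: "Methods: partitioned survival cost-effectiveness with reconstructed patient data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned survival cost-effectiveness with reconstructed patient data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

This vignette is the package's own account of the methods it implements:
the model, its assumptions, the tunable parameters and their defaults, the
synthetic data it validates against, and the numerical and design choices
made where the design was genuinely open.

## The partitioned survival model

A partitioned survival model (PSM) evaluates two treatment strategies on
three health states — progression-free (PFS), progressed disease (PD) and
death — without modelling transitions.  State occupancy at any time is
read directly off two survival curves:

* progression-free: `min(S_PFS(t), S_OS(t))`
* progressed: `S_OS(t) − S_PFS(t)` (after the clamp, never negative)
* dead: `1 − S_OS(t)`

The clamp matters only when independently fitted extrapolations cross;
occupancy then sums to one by construction (`build_trace` enforces this to
1e-9 per cycle, and errors if an evaluator leaves [0, 1]).

The trace advances in 42-day cycles — the least common multiple of the
three-weekly immunotherapy schedule and the two-weekly chemotherapy
schedule — and stops at the first cycle with fewer than 1 % of the cohort
alive (`horizon_threshold = 0.01`) or at a hard cap of 40 years.
Tightening the threshold to 0.1 % changes total QALYs by under 1 % on the
default synthetic fit set (tested), so the 1 % rule is an adequate
lifetime horizon.

Per cycle, the model accrues (all in `accrue_outcomes`):

* life-years and utility-weighted QALYs on the alive states
  (`u_pfs = 0.7825`, the mean of the four trial-arm EQ-5D-3L scores;
  `u_pd = 0.64`);
* drug acquisition and administration on the PFS occupancy only
  (treatment to progression), with per-drug caps on the number of
  administrations enforced by cycle index — the 200 mg q3w checkpoint
  inhibitor is capped at 35 doses, i.e. full cost in cycles 1–17, half in
  cycle 18, none after;
* follow-up cost on all alive states;
* treatment after progression on the PD occupancy (next section);
* a one-off adverse-event burden in cycle 1, undiscounted: the
  incidence-weighted sums of management costs and of disutility
  magnitudes (grade 3–4 diarrhoea, anaemia, hypokalaemia, neutropenia).

Discounting is annual at 5 % (range 0–8 %) on a day scale,
`(1 + r)^(−t/365.25)`.  The canonical internal time unit is the day, with
months at 30.4375 d and years at 365.25 d, so that inputs quoted in weeks,
months and years cannot drift apart.

**Cycle integration.** The default rule is trapezoid: each cycle
contributes the average of its start- and end-of-cycle occupancy,
discounted at the cycle midpoint.  Against the closed-form exponential
oracle (both curves exponential, constant cycle costs) this is accurate to
well under 0.5 % at 42-day cycles; a pure end-of-cycle rule
(`integration: endpoint`) is available for comparison with
worksheet-style implementations.

## Costing model

The comparator arm's first-line cost is the mixture-weighted average over
the six observed regimens (mFOLFOX, FOLFIRI, each alone or with
bevacizumab or cetuximab; weights 7.69/44.76/3.50/11.19/25.17/7.69 %).
Backbone doses follow the trial protocol (oxaliplatin 85, leucovorin 400,
5-FU 2800 total, irinotecan 180 mg/m² per two-weekly administration, three
administrations per cycle); bevacizumab is 5 mg/kg q2w; cetuximab is
250 mg/m² weekly with a 400 mg/m² loading dose, applied as a cycle-1
surcharge only.  Doses convert to milligrams at a body surface area of
1.80 m² and weight of 65 kg, and to USD at the per-mg prices of the
bundled configuration; no vial rounding is applied.  Attendances are one
per protocol visit day: 2 per cycle for q3w, 3 for q2w, plus 6 for weekly
cetuximab.

Treatment after progression is modelled as a class-weighted per-cycle cost
applied to the PD occupancy.  A PSM cannot track time-in-state per
patient, so this is the standard memoryless approximation; to avoid
checkpoint-inhibitor costs accruing indefinitely, the two ICI classes stop
contributing after a configurable 17.4 cycles (two years), prorated in the
cycle containing the cap.  Class costs use representative regimens: the
chemotherapy class is the simple average of CAPIRI, CAPOX, FOLFOX and
FOLFIRI per-cycle costs (the capecitabine-based doses — 1000 mg/m² twice
daily days 1–14 q3w, oxaliplatin 130 mg/m², irinotecan 200 mg/m² — are
standard schedules, configurable in the `dosing` section); the ICI classes
price 200 mg q3w and 240 mg q2w schedules; the VEGF and EGFR classes use
bevacizumab 5 mg/kg q2w and cetuximab 250 mg/m² weekly.
Best-supportive-care cost is fixed at zero.

The patient-assistance-programme scenario (`apply_scenario_pap`) replaces
first-line checkpoint-inhibitor acquisition with an annual fee of $11,200
prorated per cycle and capped at $22,400 lifetime.  It deliberately does
not touch the crossover (post-progression) ICI cost: programme eligibility
for crossover use is ambiguous, and the single configurable ICI duration
cap treats both arms identically.

A note on magnitudes: the configuration's checkpoint-inhibitor list price
($179.18/mg, i.e. ≈$35.8k per 200 mg dose) is taken as printed from its
source table even though it is high relative to the assistance-programme
fee it sits beside; absolute arm costs are therefore large, and the
assistance scenario changes the ICER dramatically.  The package always
reports ratios as computed from its own totals and never copies a printed
ratio.

## Pseudo-IPD reconstruction

`reconstruct_ipd` inverts the Kaplan–Meier construction from digitised
curve coordinates and a number-at-risk table.  Within each risk-table
interval the number censored is found iteratively: guess, place the
censorings inside the interval, derive integer event counts at each curve
step from the running product-limit identity
`d_i = round(n_i (1 − S_i / KM_prev))` (the running estimate carries the
realised integer counts, so rounding is cumulative and does not drift),
and correct the guess by the mismatch between the implied and published
risk set at the next boundary.  Risk-table boundaries beyond the digitised
span still constrain tail censoring.  After the last step, everyone still
at risk is censored at the final observed time.  The procedure is fully
deterministic; ties put events before censorings.

**Censoring placement.** The classical assumption spreads an interval's
censorings uniformly (interior quantile midpoints); that dialect is
available as `censoring = "uniform"`.  The default is `"adaptive"`: the
count of interval censorings consumed before each curve step is chosen —
as close to the uniform expectation as possible — to minimise the gap
between the reconstructed and input curve at that step.  Interval totals
and boundary risk-set matches are identical under both rules.  The
adaptive rule exists because administrative censoring clusters in the
sparse tail of a long-follow-up trial, where misplacing a single subject
moves the curve by roughly S/n; the test suite includes an arm on which
the uniform dialect exceeds the 0.01 round-trip tolerance while the
adaptive rule stays within it, and a twenty-arm round-trip suite that the
default passes.

Degenerate inputs: with no risk table, the weakest assumption that keeps
the algorithm defined is used — no censoring before last follow-up, with a
warning and a user-supplied cohort size.  A risk table whose counts
increase, or that implies negative censorings, raises an error naming the
interval.  An optional total event count rescales the final interval's
events by cumulative re-rounding.

Curve cleaning (`clean_curve`) is idempotent pre-processing: clamp to
[0, 1], isotonic (pool-adjacent-violators) monotonisation, deduplication
of equal times keeping the lower survival, and a (0, 1) anchor.

## Parametric fitting and extrapolation

Six families are fitted by right-censored maximum likelihood:
exponential, Weibull, Gompertz, log-logistic, log-normal and generalized
gamma.  The generalized gamma uses the (μ, σ, q) parameterisation, which
nests the log-normal at q = 0 — handled by an explicit switch at
|q| < 1e-5, where density and survival evaluate the log-normal limit —
and the Weibull at q = 1.  The Gompertz allows negative shape (improper
survival with a plateau `exp(rate/shape)`); a fit in that region logs a
message because extrapolated survival then never reaches zero and the
horizon cap binds.

Numerics: positive parameters are optimised on the log scale (q and the
Gompertz shape unconstrained); starting values are data-driven method-of-
moments on log event times, with three or more deterministic start
variants per family, BFGS search, and a Nelder–Mead polish — so refitting
identical data reproduces identical estimates.  Invalid parameter regions
return a large negative sentinel rather than raising.  The exponential
rate has the closed form events/total-time and is returned exactly.
AIC = −2ℓ + 2k and BIC = −2ℓ + k·log n use n = all records (events plus
censored), the dominant convention.  `select_model` ranks converged fits
by AIC (near-ties under 0.01 fall through to BIC; non-converged fits rank
last, flagged).

The base-case binding (`base_case_families`) assigns the generalized
gamma to overall survival in both arms and to experimental-arm PFS, and
the log-normal to comparator-arm PFS; `run_pipeline(families = "aic")`
re-selects per endpoint instead.  Curve uncertainty is deliberately not
propagated into the probabilistic analysis: the sampled quantities are the
economic inputs, matching the uncertainty analysis this package mirrors.

## Sensitivity analyses

The sensitivity registry is built from the configuration: each parameter
carries a kind (beta for probabilities and utilities, gamma for costs,
fixed for unsampled values), deterministic bounds, and sampling
parameters.  Where a row prints both explicit (α, β)/(shape, scale) and a
(mean, SE) pair, the explicit parameters win and any moment mismatch is
logged as a note — honouring printed parameters while exposing the
inconsistency.  Missing explicit parameters are derived by method of
moments: ν = m(1−m)/se² − 1, α = mν, β = (1−m)ν for the beta;
shape = (m/se)², scale = se²/m for the gamma.  Deterministic ranges follow
the ±20 % rule where the source used it, otherwise reported intervals.

One-way DSA re-evaluates the ICER at each parameter's bounds with
everything else at baseline and ranks by bar width; failed or
non-interior bounds are flagged, never dropped, and the
assistance-programme scenario is included as a row.  The PSA samples every
non-fixed parameter per iteration (500 by default) — disutilities as
magnitudes then negated, mixture weights renormalised to sum to one after
joint sampling — and records incremental cost and QALYs; the acceptability
curve is the fraction of draws with positive net monetary benefit
λ·ΔQALY − ΔCost over a $0–60,000 grid in $500 steps.  All sampling is
seeded and bit-reproducible; the pipeline derives the PSA seed from the
master seed.

Dominance handling: when incremental cost and QALYs share a sign the
comparison is interior and the ICER is their ratio; cheaper-and-at-least-
as-effective is dominant, costlier-and-no-more-effective dominated (ICER
not applicable); a zero QALY difference with non-zero cost is flagged
undefined rather than divided.  `icer_value` always carries the raw ratio
when ΔQALY ≠ 0, which is what tornado plots use.

## The synthetic trial generator

The generator emulates the study conditions the analysis assumes: two
arms of 154 subjects; experimental-arm PFS log-logistic with median 16.5
months and shape 0.63 (giving the pronounced plateau of an immunotherapy
arm: about 55 % progression-free at one year and 44 % at two);
comparator-arm PFS log-normal with median 8.2 months and log-SD 1.65
(about 41 % at one year); exponential post-progression survival with a
24-month median in both arms; uniform accrual over 24 months plus 33
months of administrative follow-up (per-subject follow-up 33–57 months,
median ≈ 45); loss to follow-up at 0.002/month.  Where the emulated trial
reports a value (medians, follow-up), the default matches it; the shape
and post-progression parameters are one-time choices a trialist would call
realistic, stated here and not revisited.

What it does not emulate: subject covariates and subgroups, crossover as
an explicit treatment switch (post-progression survival is a single
exponential, identical across arms), non-uniform accrual, or dependent
censoring.  Passing tests therefore demonstrate that the pipeline's
machinery is correct under these idealised conditions, not that any
specific published cost-effectiveness number is reproduced — reconstructed
pseudo-IPD depends on the digitised curves used, which are synthetic here.

Digitisation is emulated by sampling the step function on a regular grid
plus all step locations, adding truncated Gaussian read-off noise, and
restoring monotonicity by isotonic regression (noise must not break the
monotonicity the reconstruction assumes).

## Problem sizes and test design

The test suite exercises: hand-checkable product-limit and
pool-adjacent-violators examples; density normalisation (∫f = 1 to 1e-6)
and survival/quantile inversion for every family; the generalized-gamma
log-normal limit to 1e-6 and the Gompertz exponential limit; closed-form
exponential MLE equality; parameter recovery within 10 % from 2,000
uncensored draws per family; agreement of fitted log-likelihoods with an
independent implementation (`flexsurv`) to 1e-6; twenty seeded round-trip
arms (n = 200, six-month risk tables, ≈30 % censoring pooled across arms)
within 0.01; the closed-form discounted life-year oracle to 0.5 %;
occupancy conservation to 1e-9; exact cost-scale equivariance of the
incremental results; calibration of all 500-draw PSA sample means within
three Monte-Carlo standard errors; and the directional economics of the
synthetic base case (ICER increasing in the discount rate; the assistance
programme cutting the ICER by far more than an order of magnitude).
These sizes keep the default suite in the tens of seconds while leaving
each check statistically meaningful.

## Known limitations

* The PSM reads occupancy off marginal curves; it cannot represent
  time-in-state-dependent costs except through the cycle-indexed caps
  used here, and PFS/OS extrapolations are fitted independently (hence
  the crossing clamp).
* Subsequent-treatment cost is a memoryless per-cycle approximation with
  a shared ICI duration cap across arms.
* Synthetic base-case ICERs vary substantially with the generator seed at
  trial-sized cohorts because tail extrapolation is genuinely uncertain;
  the package reports what the fitted curves imply.
* The bundled configuration is taken as printed from its source table,
  including values whose internal arithmetic is mildly inconsistent
  (explicit beta parameters vs their stated moments; the
  checkpoint-inhibitor list price).  Inconsistencies are logged, not
  silently corrected.
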
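---
title: "Methods: a within-trial cost-utility pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a within-trial cost-utility pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`trialcea` implements a complete trial-based cost-utility analysis from a
health-service (NHS + personal social services) perspective: it costs a
complex intervention from a line-item ledger, scores EQ-5D-3L health states
into utilities, accumulates quality-adjusted life-years (QALYs), handles
missing data by deterministic zero-filling plus arm-wise multiple
imputation, adjusts costs and QALYs with generalised linear models and
recycled predictions, and quantifies decision uncertainty with a
non-parametric bootstrap, incremental cost-effectiveness ratios (ICERs) and
cost-effectiveness acceptability curves (CEACs). A seeded synthetic trial
generator reproduces the statistical structure such an analysis faces, so
every stage is testable end to end without access to any real dataset.

This vignette records the modelling choices, their defaults, and the
reasoning behind the places where the design was genuinely open.

## Intervention micro-costing

The intervention cost is assembled from a YAML ledger of line items grouped
into sections (therapist training, per-visit session costs, shared patient
equipment). Each item is `unit cost x quantity`; quantities may be
apportionment expressions evaluated against `n_participants` and
`n_sessions` (for example, a weighted vest used by one participant in five
and shared between two gives `(n_participants / 5) / 2`). Equipment that
outlives the analysis is converted to an annual equivalent cost with the
annuity factor

$$\text{annual cost} = \frac{K}{\bigl(1 - (1+r)^{-n}\bigr)/r},$$

with purchase cost $K$, discount rate $r$ (default 0.035) and lifespan $n$
years; at $r = 0$ the factor is its limit $n$. No other discounting is
applied anywhere: the analysis horizons are at most 12 months.

**Rounding convention.** Effective unit costs (after annuitization) and
resolved quantities are reported — and multiplied — at 2 decimal places,
the convention of published costing tables, where each row's sum must be
reproducible from its printed unit cost and quantity. Totals are carried at
full precision afterwards and rounded only for reporting, with half-up
(`round2()`) rather than banker's rounding, because `round(1154.895, 2)`
in floating point is 1154.89 while a costing table prints 1154.90. The
shipped default ledger (a 12-session home physiotherapy programme for 238
participants, 2016 GBP) recomputes to **£649.29 per patient**; its
individual line sums are locked by tests.

## Utilities and QALYs

EQ-5D-3L states (five dimensions, three levels) are scored by the additive
decrement model: utility $= 1$ minus a constant if any dimension exceeds
level 1, minus per-dimension level-2/level-3 decrements, minus an N3 term
if any dimension is at level 3. The value set is a data file; the shipped
default is the UK general-population time-trade-off tariff, under which the
worst state 33333 scores $-0.594$. Scoring is value-set-agnostic:
monotonicity (worsening any one dimension never increases utility) is
guaranteed by non-negative decrements and is verified exhaustively over all
243 states.

QALYs use the trapezoidal area under the utility-time curve: consecutive
assessments $a, b$ contribute $(u_a + u_b)/2 \times (t_b - t_a)/12$ years,
with a 3-month interval equal to exactly 0.25 years. Participants who die
have utility and resource use set to zero from the first scheduled
assessment *after* the death month; pre-death assessments are kept as
recorded. A missing utility inside the horizon is a precondition error —
imputation must run first.

## Missing data

Two layers, mirroring how postal resource-use questionnaires actually fail:

1. **Item-level zero-fill (deterministic).** Within a cost category and
   period, a blank item becomes zero if and only if at least one other
   item in the same category was completed — the respondent answered the
   section, so a blank means no use. If the whole category is blank it
   stays missing. Hospitalisation forms a single-item category on purpose:
   its cost is too large to zero-fill on weak evidence, so it is always
   left to imputation.
2. **Multiple imputation by chained equations with predictive mean
   matching (PMM),** run separately within each trial arm, imputing
   utilities per timepoint and cost-category totals per period (NHS
   excluding hospitalisation, hospitalisation, social care). Defaults:
   `m = 50` imputations, donor pool `k = 5`, 10 chained cycles, variables
   visited in temporal order with utilities before costs (earlier, better
   observed variables predict later ones). Each variable is regressed on
   the baseline covariate list used by the analysis models (congeniality)
   plus the current values of the other imputation variables, with a
   Bayesian draw of the regression parameters; a missing value receives
   the *observed* value of one of the `k` donors with nearest predicted
   means, ties broken at random. PMM keeps every imputed utility inside
   the value-set range and every imputed cost non-negative by
   construction. The donor count, cycle count and the handling of baseline
   covariates (generated complete; real data should be screened first) are
   package choices — standard PMM practice — since no single convention is
   universal.

The engine is implemented in the package on top of base QR least-squares;
its behaviour is pinned by property tests (donor support, positive
between-imputation variance, recovery of pre-deletion means under MAR).

## Estimation

Total cost over the horizon (category costs plus the per-patient
intervention cost for intervention-arm participants) is modelled with a
Gamma GLM, log link; QALYs with a Gaussian GLM, identity link. The
covariate set is fixed and identical for both outcomes: baseline utility,
baseline cost, age, gender, Hoehn & Yahr stage (ordered numeric), MoCA,
MMSE, diabetes, myocardial infarction, ischaemic heart disease, deep-brain
stimulation and informal-carer indicators. The log link is the robust
default for right-skewed costs; zero total costs (possible in the control
arm) are raised to the smallest positive observed cost $\times 10^{-3}$
and the adjustment count is logged, since the Gamma likelihood needs
positive outcomes.

**Gamma fitting.** IRLS as implemented in `stats::glm` can oscillate
indefinitely on heavy-tailed cost data (it never damps a step that
increases the deviance). For the log link the IRLS weights are identically
one, so the package fits the cost model with its own least-squares IRLS
plus deviance step-halving; on well-behaved data it agrees with a strictly
converged `stats::glm` (tested), and on resamples dominated by a repeated
cost outlier it converges where `glm` cycles.

**Recycled predictions.** Arm means are standardised over the pooled
covariate distribution: every participant's outcome is predicted with the
treatment indicator forced to each arm in turn and the predictions
averaged on the response scale. Both arm means therefore share one
covariate distribution, so chance imbalance contributes nothing to the
increments; with the identity link the incremental QALY equals the raw
treatment coefficient exactly (tested). Estimates are pooled over
imputations by Rubin's rule for point estimates (the mean), with the
between-imputation variance recorded.

## Uncertainty

The bootstrap resamples participants with replacement, stratified by
randomised arm with arm sizes preserved, from the original incomplete
data, and re-runs the full pipeline — zero-fill, a single fresh
imputation, outcome construction, both GLMs, recycled predictions — once
per iteration (default `B = 1000` pairs). The point estimate uses the full
`m = 50` stack on the original data. Resample-then-impute with `m = 1`
propagates imputation uncertainty into the bootstrap distribution without
an `m x B` blow-up; iterations whose pipeline fails (a degenerate
resample) are retried with a fresh draw and more than 5% failures abort
the run. The ICER is the ratio of full-precision increments, always
carrying a quadrant label and a dominance classification; a zero QALY
difference yields a tagged undefined result rather than an error. Note
that an ICER recomputed from *rounded* increments can differ noticeably
from the full-precision ratio (925/0.008 = 115,625 per unit), which is why
the pipeline never reports a bare rounded ratio.

The CEAC evaluates, at each willingness-to-pay threshold $\lambda$ on a
£0–£200,000 grid (step £500), the fraction of bootstrap pairs with
positive incremental net monetary benefit
$\lambda \Delta E - \Delta C > 0$; exact zeros count as not
cost-effective (strict inequality — the tie convention is the package's
choice). Cost-effectiveness-plane quadrants use the boundary convention
$\Delta C \ge 0 \Rightarrow$ north, $\Delta E \ge 0 \Rightarrow$ east.

## Scenarios

Configured variants of the base case:

* **Session recosting** (12 to 10 or 8 sessions) scales per-visit ledger
  items exactly by the session ratio, leaves fixed items untouched, and by
  construction leaves the QALY side bit-identical (maintained quality of
  life is the scenario's premise).
* **Complete case** drops participants with any missing analysis variable
  inside the horizon and skips imputation.
* **Routine-physiotherapy exclusion** removes those visits from costing —
  the scenario where respondents may not distinguish trial therapists from
  routine ones.
* **12-month horizon** extends the QALY integral with linear interpolation
  to month 12 and imputes all 12-month variables for participants not
  followed that far.
* **Subgroups** (UPDRS, MoCA, freezing of gait, retrospective falls) fit a
  single treatment-by-subgroup interaction model and report
  recycled-prediction increments within each level, standardising over the
  level's own covariate distribution; one interaction model keeps the
  covariate effects stable across strata (per-stratum refits would halve
  the effective sample for every nuisance coefficient). Numeric subgroup
  cut points default to the sample median — declared assumptions, since no
  canonical cuts exist.

## The synthetic generator

`simulate_trial()` emulates the conditions this kind of analysis meets: a
two-arm trial of 238 + 236 participants assessed at 0/3/6/12 months;
baseline utility approximately normal (mean 0.69, SD 0.21) with gradual
decline and assessment noise (SD 0.15), censored to $[-0.594, 1]$; small
per-timepoint intervention effects on utility (defaults 0.020 / 0.031 /
0.017 at months 3/6/12, implying an incremental 6-month QALY of ~0.008);
two-part, gamma-frailty service-use counts giving skewed zero-inflated
costs of roughly £3,000 per control participant over 6 months with a heavy
hospitalisation tail; occasional deaths (1% per period, month uniform
within the period); missing-at-random questionnaire non-response whose
probability depends on age and baseline utility, calibrated so the
*marginal* rates hit their configured values (10–21% at month 6 by arm);
3% sporadic single-item skips to feed the zero-fill rule; and 50%
attrition at 12 months.

The generator records analytic truth metadata: per-timepoint arm utility
means in closed form (mean of a censored normal), the implied incremental
QALYs by the trapezoid rule, and expected per-period category costs.
Recovery tests compare estimates against these exact values rather than
against nominal effects, so ceiling censoring does not masquerade as
estimator bias. With a nonzero death hazard the closed forms are
conditional on survival; recovery and coverage tests therefore use
death-free configurations.

What the generator does *not* emulate: real correlation between baseline
covariates and outcomes (covariates are independent noise by default, so
adjustment is exercised but not advantaged), digit heaping and recall
error in counts, informative dropout (an effect–missingness correlation
can be built by editing the generated data, as the subgroup tests do, but
is off by default), and item-level cost structure beyond the category
totals. Passing tests demonstrate the estimators are correct under the
stated mechanism, not that any real intervention is or is not
cost-effective.

## Problem sizes and numerical choices

The test suite runs its heavy checks at: 50 simulation replicates for
parameter recovery (full trial size, `m = 5` imputations) and for
bootstrap CI coverage (`B = 200`, complete data — coverage is a property
of the percentile bootstrap itself, so imputation adds nothing there);
`B = 50` on a 10-participant fixture for the exact CEAC recount. These
sizes give Monte-Carlo standard errors small enough for 3-SE checks while
keeping the default suite fast.

Other numerical conventions: one user seed fans out to fixed per-stage
sub-seeds (simulation, missingness, imputation, bootstrap), so stages are
independently reproducible and never share a stream; PMM donor ties break
randomly; rank-deficient designs drop aliased columns via pivoted QR; the
bootstrap bump for zero costs, the strict CEAC inequality and the plane
boundary convention are all documented above and pinned by tests.

## Limitations

Costs and QALYs are analysed independently (no seemingly-unrelated or
hurdle structure); no MNAR sensitivity models; no EQ-5D-5L or crosswalks;
no extrapolation beyond 12 months; no Fieller or parametric ICER
intervals; no value-of-information analysis. The shipped unit-cost table
is synthetic and illustrative — substantive analyses must supply costs
from national schedules for their base year.
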
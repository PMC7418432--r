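# trialcea

Within-trial cost-utility analysis in R: micro-costing, EQ-5D-3L QALYs,
multiple imputation, GLM adjustment with recycled predictions, and
bootstrap ICER/CEAC uncertainty analysis.

`trialcea` is aimed at health economists analysing a two-arm randomised
trial from a health-service perspective (NHS + personal social services),
and at methodologists who want a fully simulatable, testable version of
that pipeline. Every stage is driven by plain-text configuration (YAML
ledgers, unit-cost tables, value sets) and a seeded synthetic trial
generator stands in for participant data, so the entire analysis can be
exercised, tested and benchmarked without any real dataset.

## The analysis

For arms $a \in \{\text{control}, \text{intervention}\}$ the pipeline
estimates adjusted mean costs $\bar C_a$ and QALYs $\bar E_a$ and reports

$$\text{ICER} = \frac{\Delta C}{\Delta E}
             = \frac{\bar C_1 - \bar C_0}{\bar E_1 - \bar E_0},$$

with decision uncertainty summarised by the probability of positive
incremental net monetary benefit, $\Pr(\lambda\,\Delta E - \Delta C > 0)$,
across willingness-to-pay thresholds $\lambda \in$ £0–£200,000 (the CEAC).
The stages:

1. **Intervention micro-costing** — line-item ledger with apportionment
   rules and annuitization of equipment over its lifespan at a 3.5%
   discount rate: annual cost $= K \big/ \frac{1-(1+r)^{-n}}{r}$.
2. **Utilities and QALYs** — EQ-5D-3L states scored with a configurable
   value set (UK TTO tariff shipped; worst state 33333 scores −0.594);
   QALYs by trapezoidal area under the utility-time curve, with utility
   and resource use set to zero from the first assessment after death.
3. **Missing data** — deterministic item-level zero-fill inside completed
   questionnaire sections, then multiple imputation by chained equations
   with predictive mean matching (m = 50, k = 5 donors), run separately
   within each arm at the utility-value and cost-category level.
4. **Estimation** — Gamma (log link) GLM for total costs, Gaussian GLM for
   QALYs, a fixed baseline covariate set, and recycled predictions
   (marginal standardization) so both arm means share one covariate
   distribution; estimates pooled over imputations.
5. **Uncertainty** — 1000-iteration non-parametric bootstrap of the whole
   pipeline, stratified by arm; percentile CIs, cost-effectiveness plane
   quadrants, CEAC.
6. **Scenarios** — session-count recosting (QALYs held fixed), complete
   case, routine-physiotherapy exclusion, 12-month horizon, and subgroup
   analyses via treatment-by-subgroup interaction models.

See `vignettes/cost-utility-pipeline.Rmd` for the full methods account.

## Worked example

```r
library(trialcea)

# a synthetic 474-participant trial with realistic missingness
cfg   <- sim_config(seed = 2026)
trial <- apply_missingness(simulate_trial(cfg), cfg)

res <- run_cea(trial, B = 400, m = 20, seed = 7)  # ~3 min on one CPU
print(res)
```

```
Within-trial cost-utility analysis (intervention cost 649.29 GBP/patient)
Cost-utility estimate over 6 months (B = 400 bootstrap pairs)
  delta cost : 1289.10 GBP (95% CI 187.88 to 2510.11)
  delta QALY : 0.0054 (95% CI -0.0038 to 0.0136)
ICER: 238303 GBP/QALY [NE: more costly, more effective]
  P(cost-effective at 30,000 GBP/QALY) = 0.025
```

Reading the output: the intervention costs £649.29 per patient by
micro-costing; over six months it adds about £1,289 per participant in
total (intervention plus routine care) for a gain of 0.0054 QALYs — about
two days of full health — giving an ICER far above conventional
willingness-to-pay thresholds, with only a 2.5% chance of being
cost-effective at £30,000/QALY. `ce_plane_quadrants(res$estimate)` shows
~88% of bootstrap pairs in the north-east quadrant (costlier, more
effective) and essentially all in the northern half.

The ledger audit, bootstrap pairs, CEAC table and a reproducibility
manifest are written as CSV/JSON by `write_cea_result(res, "out/")`. A thin
command-line front-end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "trialcea.R", package = "trialcea"))') \
  simulate --seed 7 --out data/
```

with commands `simulate`, `cost`, `analyze` and `scenarios`.

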
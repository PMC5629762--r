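# imcost

Survey-weighted cost estimation and Bayesian hierarchical regression for
facility-level costing studies of routine infant immunization.

## The problem

Multi-country immunization costing surveys enrol a few hundred facilities
through multi-stage cluster samples and record, per site, the total annual
cost of delivering routine infant immunization (2011 USD), the annual
service volume (doses delivered; children completing DTP3), and operating
characteristics: ownership, hospital status, outreach share, management
share, local antenatal-care coverage, local wealth, per-capita GDP. Two
analyses follow:

1. **Average costs** per site, per dose and per DTP3, by country — as
   program-level (volume-weighted) and simple averages, survey-weighted,
   with and without above-site (subnational/national administration)
   markups, and with multi-stage bootstrap confidence intervals that
   resample provinces then sites within countries.
2. **Cost determinants** via a ladder of Bayesian hierarchical
   regressions of log total site cost,

   log C_i ~ Normal(β₀ + xᵢ'β + α_c(i) + α_p(i) + γ_c(i)·z(log V_i), σ),

   with country and province random intercepts, country-specific random
   slopes on log volume, standardized predictors, and WAIC for model
   comparison — then post-estimation economics: Duan-smearing
   retransformed cost curves, first differences (percent change in cost
   per dose for defined predictor changes), output elasticities
   (1 / (d log C / d log V); values above 1 mean economies of scale), and
   top-vs-bottom volume-quintile contrasts.

Because the real pooled survey data live in an external archive, the
package ships a fully specified synthetic-data generator whose preset
emulates the six-country, 316-site sample (site counts 45/50/71/50/49/51,
GDP $531–$2277, right-skewed volumes, residual SD 0.35, noisy coverage
denominators). Every estimator is exercised against this known ground
truth.

## Worked example

```r
library(imcost)

d   <- generate_dataset(epic_like_config(seed = 3))
tab <- d$table

weighted_average_cost(tab, "dose", by = "pooled")$point
#> [1] 4.12  # program-level cost per dose, 2011 USD

fits <- lapply(1:5, function(k)
  fit_model(tab, model_preset(k),
            mcmc_control(seed = 3 + k, thin = if (k < 3) 5 else 1)))
compare_models(setNames(fits, paste("Model", 1:5)))[, 1:3]
#>     model     waic delta_waic
#> 1 Model 5 218.4        0.0
#> 2 Model 4 226.7        8.4
#> 3 Model 3 250.3       31.9
#> 4 Model 2 371.8      153.4
#> 5 Model 1 741.7      523.3
```

The WAIC ladder falls monotonically — volume terms explain most of the
variance, site characteristics and country volume slopes add the rest —
and the best model's economics read directly:

```r
best <- fits[[5]]
output_elasticity(best)[7, ]
#>   country elasticity ci_low ci_high
#> 7  pooled       1.76   1.65    1.89   # >1: economies of scale

volume_doubling_difference(best)[7, c("scope", "percent_change")]
#>                    scope percent_change
#> 7 overall (country mean)          -25.2  # doubling volume cuts cost/dose

first_difference(best, "hospital")
#>           contrast   scope percent_change ci_low ci_high
#> 1 hospital: 0 -> 1 overall           25.8    9.9    43.8
```

A hospital site costs ~26% more per dose than a comparable non-hospital
site; doubling a site's volume cuts its cost per dose by ~25%; the
generator's true elasticity (≈1.4–1.8 across countries, given its random
slopes) sits inside the reported intervals.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
preset and write tables under `results/` (set `IMCOST_SEED` to change the
seed):

| script | writes |
|---|---|
| `01_simulate.R` | `site_table.csv`, ground-truth side-car JSON |
| `02_cost_summaries.R` | average-cost table with bootstrap CIs, dispersion stats |
| `03_fit_models.R` | WAIC ranking, coefficient table, recovery report |
| `04_post_estimation.R` | first differences, elasticities, quintile contrasts, cost-curve data and figure |
| `05_robustness.R` | fixed-effects / Student-t / non-informative / DTP3-volume / coverage variants |

`run_pipeline(pipeline_config(out_dir = "results"))` performs the same
stages programmatically with a checksummed run manifest. The methods
vignette (`vignettes/immunization-costing.Rmd`) documents the model,
priors, numerical choices and the generator's scope.

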
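---
title: "Modelling the cost determinants of routine infant immunization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost determinants of routine infant immunization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Facility-level costing surveys of routine infant immunization collect, for
each enrolled site, the total annual economic cost of delivering vaccines
to children under one, the annual service volume (doses delivered, and
children completing the third DTP dose, "DTP3"), and a set of operating
characteristics. Two questions drive the analysis:

1. **What do average costs look like?** Per site, per dose, and per DTP3,
   by country, with uncertainty that respects the multi-stage cluster
   sample through which sites were selected.
2. **What explains the (large) variation between sites?** In particular,
   how strongly do unit costs fall with service volume — the economies of
   scale that dominate every other predictor.

`imcost` implements this analysis end to end, together with a synthetic
data generator that emulates a six-country survey of 316 sites so that
every stage can be tested against known ground truth without any external
data.

## Average-cost estimators

For sites $i$ with survey weight $w_i$ (inverse of the overall sampling
inclusion probability), cost $C_i$ and output $O_i$ (doses, DTP3, or 1 for
per-site costs), two estimators are reported:

* the **program-level (volume-weighted) average**
  $\sum_i w_i C_i \big/ \sum_i w_i O_i$, the cost per outcome of the
  program as a whole; and
* the **simple average** $\sum_i w_i (C_i/O_i) \big/ \sum_i w_i$, which
  gives every site equal design-weighted influence.

The simple average exceeds the program-level one whenever small sites have
higher unit costs, which is the empirically dominant pattern; the gap
between the two is itself an informative summary. Both are survey-weighted
throughout.

Above-site (subnational and national administration) costs are applied as
a fixed per-country markup on site-level costs with the additive
convention: a subnational markup $m_s$ and national markup $m_n$ scale a
summary by $1 + m_s + m_n$. This matches the published markup tables,
where the "total" markup equals the sum of the two components.

Uncertainty comes from a **multi-stage bootstrap**: within each country,
provinces are resampled with replacement, then sites within each selected
province, carrying their weights; the interval is the percentile interval
of the replicate distribution. The percentile method is the simplest
defensible reading of "multi-stage bootstrap"; BCa or studentized versions
were deliberately not layered on top. A country contributing a single
province degenerates to site-level resampling with a warning. Whether the
original study recomputed weights per replicate is unknowable from the
text; replicates here carry the original weights.

## The hierarchical cost regression

The regression ladder models the natural log of total site-level cost
(excluding above-site costs):

$$\log C_i \sim \mathrm{Normal}(\eta_i, \sigma), \qquad
\eta_i = \beta_0 + x_i^\top \beta + \alpha_{c(i)} + \alpha_{p(i)}
+ \gamma_{c(i)}\, z(\log V_i)$$

with country intercepts $\alpha_c \sim N(0, \sigma_c^2)$, province
intercepts $\alpha_p \sim N(0, \sigma_p^2)$, and (Model 5) country-level
random slopes $\gamma_c \sim N(0, \sigma_\gamma^2)$ on standardized log
volume. The five presets are strictly nested: Model 1 is intercept plus
country/province intercepts; Model 2 adds $\log V$ and its square; Model 3
adds log per-capita GDP and site characteristics; Model 4 adds
operating-environment variables; Model 5 adds the country volume slopes.
Model fit is compared by WAIC,
$-2\left(\sum_j \log \tfrac1S \sum_s e^{\ell_{sj}} -
\sum_j \mathrm{Var}_s\, \ell_{sj}\right)$, computed from pointwise
posterior log-likelihoods in log space.

**Standardization.** Continuous predictors are z-scored on the pooled
estimation sample, so coefficients read as the change in log cost per 1 SD
change in the predictor. Binary predictors stay on the 0/1 scale — the
published footnote qualifies standardization as applying to continuous
variables, and a 1 SD change in a dummy has no subject-matter meaning. A
switch (`standardize_binary`) restores all-column scaling for
sensitivity. The squared-volume term is the z-score of the square of the
z-scored log volume (`quad_style = "z_of_zsq"`), preserving the per-SD
reading of both volume coefficients; squaring the raw log volume first is
available by flag. The standardization info is stored with the fit and
inverts the transform exactly, which the post-estimation derivatives rely
on.

**Survey weights are not used in the likelihood.** The hierarchy itself —
country and province levels mirroring the sampling stages — is the
mechanism that accounts for the multi-stage design. This is the central
modelling interpretation; weights still enter every design-based
average-cost estimate.

**Priors.** Weakly informative defaults: Normal(0, 2.5) on standardized
coefficients and the intercept, half-Normal(0, 1) on random-effect SDs and
$\sigma$. The non-informative variant uses Normal(0, $10^3$ SD)
coefficients and Uniform(0, 100) scales. The robust variant replaces the
Gaussian residual with Student-t (unknown $\nu \sim U(2, 100)$),
implemented as a normal scale mixture
($y_i \sim N(\eta_i, \sigma^2/\lambda_i)$,
$\lambda_i \sim \mathrm{Gamma}(\nu/2, \nu/2)$) so that the sampler's
conjugate block updates still apply.

**Sampling.** Posteriors are drawn with JAGS (Gibbs/slice sampling with
the `glm` module's block updates), 4 chains, 500 adaptation + 500 burn-in
iterations and 1000 kept draws per chain by default. Two numerical choices
matter and are worth recording:

* *Hierarchical centring.* Log GDP is constant within country, so it
  trades off one-for-one against the country intercepts. The model
  therefore places country-constant predictors in the country-level mean,
  $\alpha_c \sim N(x_c^\top \beta_c, \sigma_c^2)$ — the marginal model is
  unchanged, but componentwise sampling of the original parameterization
  effectively never converges while the centred one mixes in seconds.
* *Recentring for reporting.* With six countries, the split between the
  intercept and the mean of the country effects is only weakly
  identified. Draws are recentred after sampling (group means swept into
  the intercept, the mean country slope into the volume coefficient), and
  convergence diagnostics are computed on the recentred parameters. The
  fit fails hard if any recentred R-hat exceeds 1.05 (1.01 is advisory);
  the sparse Models 1–2 need modest thinning (`thin = 5`) for their
  variance components to clear this bar.

"Fixed" country effects are implemented as unpooled country effects under
the coefficient prior rather than flat reference-coded dummies: alongside
log GDP a flat parameterization would be non-identified, and the weakly
informative prior is what makes the published fixed-vs-random comparison
meaningful.

**Error-in-variables coverage.** Reported DTP3 coverage divides DTP3 by a
catchment population estimate of poor quality (observed values exceed
100%). The EIV variant treats observed coverage as latent true coverage
$\kappa_i \sim \mathrm{Beta}(2,2)$ times multiplicative lognormal error
with unknown SD, and enters the standardized latent value in the linear
predictor. Top-coding (`top_code`, capping at 100%) and log catchment
population are the two simpler treatments.

## Post-estimation economics

All post-estimation quantities are computed per posterior draw and
summarized by the mean and equal-tailed 95% interval (empirical 2.5/97.5
percentiles).

* **Smearing.** Absolute-scale predictions multiply $e^{\eta}$ by the Duan
  smearing factor $\phi = \frac1n \sum_i e^{r_i}$ computed from that
  draw's log-scale residuals (pooled by default; per-country by option).
  Cost *ratios* — every first difference — are invariant to $\phi$.
* **First differences.** The percent change in cost per dose for a defined
  predictor change; continuous predictors default to the 25th→75th
  percentile of the sample, volume contrasts double each base volume
  (country bases are the median observed volume at a typical-site
  profile). A constant raw-scale volume slope $b$ gives the closed form
  $2^{b-1}-1$ for doubling, used as an exact test. The "overall" row is
  reported both as the average over countries and as the per-site average,
  since the published table does not say which was used.
* **Output elasticity.** At each site, $1/(d\log C / d\log V)$ with the
  derivative assembled analytically on the raw scale from the linear,
  quadratic and country-slope terms via the stored standardization
  constants (the scale on which the published derivative was evaluated is
  unstated; the raw scale is the economically meaningful one). Site values
  are averaged within country per draw — the average of reciprocals, with
  the reciprocal-of-average variant by flag. Values above 1 indicate
  economies of scale.
* **Volume-quintile contrasts.** Model-predicted unit cost at each site's
  observed volume and covariates, compared between the top and bottom
  within-country volume quintiles; smearing factors cancel in the ratio.

## The synthetic-data generator

The generator is first-class, tested code, and its preset *is* the study
condition for every simulation-based check: 6 countries with 45, 50, 71,
50, 49 and 51 sites nested in 7–9 provinces, per-capita GDP $531–$2277,
covariate marginals (rural/government/hospital frequencies, ANC4, wealth
ratio, outreach and management fractions, DTP3-per-dose) matched to the
published sample characteristics, and lognormal dose volumes
moment-matched to each country's mean and SD of annual doses — the
simplest right-skewed family consistent with the log-linear model. DTP3 is
a beta-distributed fraction of doses with the published mean ratio
(~0.08–0.12). True raw-scale coefficients give a volume derivative near
0.7 at typical volumes (elasticity ≈ 1.4, inside the published 1.27–2.52
range), residual SD 0.35, and random-effect SDs 0.25/0.15/0.10
(country/province/slope). Mean log cost under the preset is ≈ 9.5,
matching the published intercept, and per-dose costs land in the published
$2–$16 range.

Coverage error is multiplicative lognormal on the *denominator* (reported
catchment = true catchment × error, SD 0.30 on the log scale), with DTP3
counts treated as accurate — the published attribution is inaccurate
population estimates. This reproduces the >100% observed-coverage
pathology at a realistic rate (~25% of sites).

Survey weights come from an explicit two-stage design:
`sample_survey_design()` draws provinces then sites by simple random
sampling without replacement at given fractions and sets weights to
inverse inclusion probabilities (Horvitz–Thompson unbiased, verified by
simulation). The real study's sampling probabilities are not published, so
this equal-probability design is a stand-in and is flagged as such; the
preset uses a census (fractions 1, 1) so that site counts are exact and
weights are 1.

One master seed controls generation, with per-country sub-streams derived
deterministically so that a country's data are reproducible under
reordering.

**What the generator does not emulate:** the real cost-ingredient
construction (overheads, amortization, salary loading), informative
sampling probabilities, missingness patterns (the optional covariates are
generated for all sites), cross-covariate correlation beyond what the
cost model induces, and any model misspecification — passing recovery
tests therefore shows the estimation machinery is correct, not that the
Model 5 functional form is right for real facilities.

## Problem sizes and test design

Simulation-based checks run at deliberately chosen sizes: parameter
recovery and elasticity recovery use 20 replicates of the full 316-site
preset with 4×1000 kept draws; the WAIC-ranking property uses 20
replicates with 2×500 draws (ranking gaps between the presets are two
orders of magnitude larger than WAIC Monte-Carlo noise); bootstrap
interval coverage uses 500 fresh frames from a 3-country, 32-province DGP
with 2000 replicates each. The coverage experiment is *design-based*: the
estimand is each frame's own program-level cost per dose, because the
within-country bootstrap conditions on (rather than resamples) the
realized country effects. Sampling fractions (0.25, 0.4) keep the
finite-population correction — which the percentile bootstrap ignores —
small relative to sampling noise.

## Known limitations

* WAIC values on synthetic data are not comparable to the published ones
  (different realized data); only the ordering behaviour is.
* The bootstrap's degenerate single-province fallback understates
  between-province uncertainty for such countries.
* The inpatient-beds category enters as an ordinal numeric rather than
  two dummies.
* Country contrasts "versus the overall mean" depend on an evaluation
  profile the source does not fully specify; the implementation evaluates
  the country intercept, slope contribution at the country median volume,
  and GDP term against the unweighted cross-country mean of the same.
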
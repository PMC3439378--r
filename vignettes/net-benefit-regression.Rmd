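---
title: "Net-benefit regression: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net-benefit regression: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbcea)
```

## The model

A two-arm economic evaluation observes, for each household $i$, a cost
$C_i \ge 0$, an effect $E_i$ (here binary: did the household use health
services), a treatment indicator $t_i$ (1 = member of the insurance
scheme) and covariates $x_{ij}$. The classical summary is the incremental
cost-effectiveness ratio $\mathrm{ICER} = \Delta C / \Delta E$, the ratio
of the between-arm differences in mean cost and mean effect.

For a ceiling ratio $\lambda$ — the most a decision maker is willing to
pay per unit of effect — the decision rule "the intervention is
cost-effective iff $\mathrm{ICER} < \lambda$" can be linearised. Each
record's net monetary benefit is
$$NB_i(\lambda) = \lambda E_i - C_i,$$
and the incremental net benefit $\delta(\lambda)$ is estimated as the
treatment coefficient of the OLS regression
$$NB_i = \alpha + \delta t_i + \varepsilon_i.$$
Because OLS on a dummy reproduces group means, the simple-model
$\hat\delta(\lambda) = \lambda\,\Delta E - \Delta C$ *exactly*, for every
$\lambda$; it is affine in $\lambda$ and crosses zero at the sample ICER.
The package tests this identity rather than assuming it.

Covariates enter as main effects, optionally with treatment-by-covariate
products:
$$NB_i = \alpha + \textstyle\sum_j \beta_j x_{ij} + \delta t_i +
  \sum_j \gamma_j\, t_i x_{ij} + \varepsilon_i,$$
where the $\gamma_j$ measure how the incremental net benefit varies at the
margin of each covariate. (Some published statements of the interaction
model omit $t_i$ from the product term; the surrounding text makes clear
the products are treatment-by-covariate, and that is what `fit_nb_adjusted(...,
interactions = TRUE)` fits.)

Inference is homoskedastic OLS by default: two-sided p-values from the $t$
distribution on the residual degrees of freedom. The p-value on $\delta$
only needs to be one-sided to test whether the incremental net benefit is
positive, so the one-sided p is half the two-sided one, and the
probability that the intervention is cost-effective at $\lambda$ is
$$P(\lambda) = \begin{cases} 1 - p/2 & \hat\delta > 0\\ p/2 & \hat\delta < 0\\
  0.5 & \hat\delta = 0. \end{cases}$$
The sign rule is undefined at $\hat\delta = 0$; 0.5 is the continuous
limit from both sides, and makes $P(\lambda) = 0.5$ hold exactly at the
sample ICER. Plotting $P(\lambda)$ over a grid gives the
cost-effectiveness acceptability curve (CEAC). No multiplicity adjustment
is applied across grid points: each $\lambda$ is a profile point of one
decision quantity, not a separate hypothesis.

## Assumptions and their consequences

* **Homoskedasticity.** The default SEs pool residual variance across
  arms. With a degenerate comparison-arm cost (a constant benefit-package
  cost), the pooled SE of $\Delta C$ is driven entirely by the
  intervention arm's cost spread scaled by the pooled formula — this is
  what reproduces published SEs such as 372 for the cost difference.
  Heteroskedasticity-robust (HC1) SEs are available behind
  `robust = TRUE` for sensitivity analysis; they are deliberately off by
  default.
* **t-based p-values.** OLS software reports $t$-tests; with n in the
  hundreds the difference from the normal is negligible, but the $t$ is
  what the fitted regression actually justifies.
* **Linear interpolation on the curve.** The CEAC ICER and confidence
  limits are first crossings of 0.5 and of $(1 \pm \mathrm{level})/2$ in
  grid order, linearly interpolated on $(\lambda, P)$ with no smoothing.
  Monotonicity of $P(\lambda)$ is *not* assumed; on pathological data a
  curve may cross a threshold more than once, and the first crossing is
  reported. A threshold never reached inside the grid yields an open
  bound (`NA`).

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| ceiling grid | currency per unit effect | 0–2,500,000 XOF, step 100,000 | brackets plausible willingness-to-pay around the ~433,000 sample ICER |
| confidence level | — | 0.95 | conventional two-sided 95% interval |
| `robust` | — | `FALSE` | homoskedastic OLS is the reference analysis |
| asset quintile coding | — | one ordinal term | a single one-degree-of-freedom wealth gradient; `quintile_indicators = TRUE` relaxes it |
| missing covariates | — | complete-case with logged drop count | transparent, and the estimand is unchanged when missingness is unrelated to arm |

Effects are kept as proportions internally; ICERs are reported both per
unit effect and per percentage point (÷100) to avoid silent factor-100
confusion between the two conventions.

## What the synthetic generator emulates

`default_nouna_config()` encodes the published structure of the 2007 Nouna
CBHI household survey: 364 member and 981 non-member households;
utilisation 85.4% vs 71.4%; non-member cost constant at 9630 XOF (the
costed benefit package); member costs normal with mean 70253 and SD 11658
XOF, truncated at zero (the mean is ~6 SDs above zero, so truncation is
cosmetic — the family is the simplest one matching the two published
moments); covariate prevalences per arm as published (education 216/364 vs
380/982, town residence 230/364 vs 394/982, the published asset-quintile
weights, head-of-household ages ~N(50.8, 15) vs N(49.6, 15) — the age SD
is not published; 15 years is a realistic survey spread and age is never a
target quantity). The published tables are internally inconsistent about
arm totals (363+981 vs 364+982 vs "N = 1344"); the generator default uses
364/981 and the worked-example fixtures use the use-count version 363/310
and 981/700 where those counts are the published inputs.

Within an arm, cost and effect are drawn independently. This matches the
published standard errors under the homoskedastic fit; no joint
cost-effect distribution is published that would identify a correlation.
Covariates are likewise independent of cost and effect within arm — which
is exactly why the adjusted coefficients of the published Table 7 (whose
covariate *joint* distribution with membership is not printed) are matched
only qualitatively, not numerically.

With `exact_moments = TRUE` the generator matches realized moments
exactly: arm effect counts are `round(n·p)` assigned to the leading
records, and member costs are affinely rescaled to the configured sample
mean/SD after within-effect-group mean equalisation, which makes the
sample covariance between cost and effect exactly zero. The
orthogonalisation is a deliberate strengthening: it makes residual
variances — hence SEs, p-values and probabilities — deterministic
functions of the configuration, so worked examples do not wobble with the
seed. Covariate counts are also made exact (largest-remainder rounding for
the quintiles), with randomly permuted placement.

What passing tests on these data do **not** show about real data:
right-skewed cost distributions (real health costs are usually lognormal-
ish; the normal family here matches two moments only), cost-effect and
covariate-outcome dependence, clustered or longitudinal structure, and
informative missingness are all absent by construction.

## Numerical choices and degenerate inputs

* SDs use the $n-1$ denominator throughout; a single-record arm reports
  SD/SE as `NA` rather than 0, and fitting requires at least two records
  per arm.
* A zero-residual-variance fit (constant net benefit within each arm) is
  returned with SE 0 and p-values flagged `NA` via the `degenerate` field
  instead of raising, so grid sweeps can handle it explicitly; curve
  crossings skip `NA` probabilities.
* Rank-deficient adjusted designs raise an error naming the aliased
  columns rather than silently dropping them.
* Ceiling grids are sorted, de-duplicated and validated non-negative;
  $\delta(\lambda)$ being affine means three grid points determine the
  simple-model curve, which the tests exploit as a regression-free check.
* The generator restores the session RNG state on exit, so analysis code
  around it is unaffected.

## Problem sizes used in the checks

The test suite works at the survey's own scale (~1,345 records) for the
worked examples, 5,000–50,000 records per arm for asymptotic sanity
checks, and 200 replicates of 150 records per arm for the
confidence-interval coverage study on a 25,000-XOF grid — sizes chosen so
each property is measured with enough precision to be meaningful (3
binomial SEs around nominal coverage) while the whole suite stays
desk-scale.

## Known limitations

* One-level (unclustered) records only; no multiple imputation — missing
  covariate values are dropped per model with a logged count.
* Binary or non-negative continuous effects; no QALY-style preference
  weighting beyond the ceiling-ratio conversion itself.
* CEAC confidence intervals are probability-threshold crossings
  (Fieller-flavoured, exact under the model); bootstrap and Bayesian
  CEACs are out of scope.
* The adjusted-model worked numbers of the source survey are not exactly
  reproducible from published moments (see above); they are covered by
  direction and identity properties instead.
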
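---
title: "Dietary inflammation and biological aging: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary inflammation and biological aging: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`inflammage` estimates the association between the inflammatory potential
of diet and biological age acceleration. This vignette is the package's
account of the science it implements: the models and their assumptions,
the parameters that matter, what the synthetic cohort does and does not
emulate, and the choices we made where the design was genuinely open.

## 1. The exposure scores

**DII / E-DII.** For each food parameter $j$ with reported daily intake
$x_j$, a z-score $z_j = (x_j - \mu_j)/\sigma_j$ is formed against a global
reference mean and SD, mapped to a *centered proportion*
$c_j = 2\Phi(z_j) - 1 \in (-1, 1)$, and weighted by the parameter's
inflammatory effect score $w_j$; the DII is $\sum_j w_j c_j$. The
energy-adjusted E-DII applies the same construction to intakes expressed
per 1000 kcal (the density method) against an energy-adjusted reference
database, which makes it invariant under proportional scaling of the whole
diet and its energy. The published methodology describes the centered
percentile verbally; we implement it as $2\Phi(z)-1$, the smooth,
symmetric, strictly increasing map that reproduces its stated properties
(zero at the reference mean, bounded contributions $|w_j c_j| < |w_j|$).

**DIS.** The Dietary Inflammation Score is
$\sum_k w_k (x_k - \mu_k)/\sigma_k$ over 19 components: 18 whole-food and
beverage groups plus one composite micronutrient-supplement group.

Assumptions and conventions:

* *Missing parameters contribute zero* — equivalent to an intake at the
  reference mean, the conservative null; a subject with no dietary data at
  all gets `NA`, not 0.
* *Standardization* of both scores (sample mean/SD) happens on the
  analytic sample after exclusions and before imputation — the exposures
  are complete by then, so the SD unit is well defined and identical
  across imputed datasets. Effects read as years of Δage per 1 SD of
  score.
* *Quartiles* are rank-based; tied subjects share the quartile of their
  mean rank, and when $n \bmod 4 \ne 0$ the extra subjects go to the lower
  quartiles first.
* The shipped registries are **synthetic illustrative values** (realistic
  scales, literature-consistent signs); the genuine global comparative
  database and DIS weights are proprietary and can be supplied as
  drop-in CSV files.

## 2. The biological-age clock

Biological age is the prediction of a feed-forward neural network
regressing chronological age on 36 circulating biomarkers plus sex and
recruiting center (38 input features); $\Delta\mathrm{age} =
\mathrm{BA} - \mathrm{CA}$, computed on a held-out 20% test partition
after training on the remaining 80% (`floor(0.8 n)` training rows; with
$n = 23{,}858$ quality-controlled records the test partition is 4,772).

Architecture and training (`bioage_config()`):

* one hidden layer (default 8 logistic units) **plus skip-layer
  connections**, linear output. The skip connections guarantee the network
  contains the ordinary linear model as a special case, which is the
  dominant part of the signal at these scales; the source protocol's exact
  deep architecture lives in its companion work and is treated here as
  configuration.
* squared-error loss on chronological age, quasi-Newton (BFGS)
  optimization; `epochs` (default 1000) caps optimizer iterations. There
  is no early stopping; mild weight decay (default $10^{-3}$) regularizes
  instead.
* inputs standardized with training-set moments; **the age label is
  standardized too** — optimizing on raw years leaves the quasi-Newton
  search badly conditioned and visibly short of convergence, while the
  standardized problem converges well before the iteration cap.
* the loss surface of a small MLP has local optima, so training runs
  `restarts` (default 3) seeded initializations and keeps the lowest
  training loss; everything is deterministic given the seed.
* row-level quality control: rows with more than `max_missing_biomarkers`
  (default 6) missing markers are dropped; the rest are median-imputed
  with training-set medians.

Permutation importance shuffles one input column at a time on the
evaluation table and reports the relative loss increase
$(\mathrm{MSE}_{\pi} - \mathrm{MSE}_0)/\mathrm{MSE}_0$, averaged over
`n_permutations` shuffles; features at or above a 5% loss drop are flagged
influential.

## 3. Eligibility, covariates, descriptive tables

Exclusions (union semantics, idempotent, per-rule counts reported):
missing dietary data; implausible energy intake — below 800 or above
4000 kcal/d in men, below 500 or above 3500 kcal/d in women, boundary
values retained; unreliable medical or dietary questionnaires (boolean
flags supplied with the data; no operational definition exists, so the
synthetic generator plants them at configured rates).

BMI classes: normal ($\le 25$ kg/m²), overweight ($>25$ and $<30$), obese
($\ge 30$). Leisure-time physical activity is consumed as MET-h/d, not
derived. Quartile descriptive tables report means (SD) or column
percentages with p-values adjusted for sex and age (plus energy for DIS):
linear regression on the quartile index for continuous rows, binomial or
multinomial logistic likelihood-ratio tests for categorical rows — the
source protocol states only "adjusted for gender and chronological age",
so the regression form is our concretization.

## 4. Imputation and pooled inference

Missing covariates are imputed $m = 10$ times (`impute()`):
Bayesian-draw normal linear regression for continuous variables,
posterior-draw logistic regression for binary ones, nested dichotomies of
logistics for multi-level categoricals. Every conditional model uses only
*complete* predictors — the outcome Δage, the standardized score(s), age,
sex and energy — so a single pass per variable is exact and no chaining
iterations are required. This is deliberately leaner than full chained
equations: it is congenial for the exposure analysis (outcome and exposure
are in every imputation model) under the MCAR covariate missingness the
generator produces, at a fraction of the cost. Covariate–covariate
correlations are not used for imputation; with per-covariate missingness
rates of order 0.1–2% this loses essentially nothing.

Structural levels are respected: menopausal status and hormone therapy
are imputed among women only; men stay at `not_applicable`. In the
regressions these two variables enter as yes/no indicators (men = no):
keeping the 3-level factor alongside sex would make the design exactly
rank-deficient, since the female indicator equals the sum of the pre- and
post-menopausal indicators.

Rubin pooling: $\bar q = m^{-1}\sum q_i$, $W = m^{-1}\sum U_i$,
$B = \mathrm{var}(q_i)$, $T = W + (1 + 1/m)B$, with Barnard–Rubin
small-sample degrees of freedom (collapsing to the complete-data df when
$B = 0$, so zero missingness reproduces the single fit exactly).
Interaction tests pool the score-by-modifier product coefficients with the
multivariate $D_1$ combination (within-covariance inflated by the average
relative increase in variance, F reference). Subgroup analyses refit
within strata — sex; age at the sample median; the three BMI classes;
smoking status; comorbidity none vs ≥ 1 — removing the stratifier from the
covariate set; the modifiers for interaction tests use these same
categorical strata. Covariates that become constant or perfectly collinear
in a restricted stratum (menopausal status among the over-70s coincides
with sex) are dropped there with a message, while the user-facing
`fit_model()` keeps a strict rank-deficiency error. Sensitivity analyses
remove one comorbidity at a time and re-estimate on the age-restricted
subsets at the 65- and 70-year cut-offs, skipping subsets below a
configurable size floor.

## 5. The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws, deterministically per seed:

* **Demographics.** Age from a normal distribution with mean 55.6 y and
  SD 11.6 y truncated to the 35–90 y recruitment range (matching the
  reference cohort's printed moments; truncation leaves an SD of
  ~10.6 y); sex Bernoulli with 52% men; a categorical recruiting center.
* **Diet.** Log-normal intakes for all 34 food parameters and 19 DIS
  components, with marginal means/SDs tied to the registry references, a
  shared energy latent (energy itself normal, mean 2080, SD 575 kcal/d,
  truncated to the sex-specific plausibility bounds), and a latent
  pro-inflammatory factor that tilts pro-inflammatory parameters up and
  anti-inflammatory ones down. The latent factor loads negatively on age
  and positively on male sex, reproducing the younger, more-male
  composition of top score quartiles. A configured fraction of records is
  drawn outside the energy plausibility bounds; reliability flags and
  per-covariate MCAR missingness (defaults matching the reference missing
  counts, e.g. 102/4510 for hormone therapy) complete the picture.
* **Biomarkers.** Affine in age and sex plus Gaussian noise, scaled so
  about a quarter of the panel is strongly age-linked (per-marker age
  correlation ≈ 0.75) and the rest weakly (≈ 0.2) — enough for a clock
  with test-set $r(\mathrm{BA}, \mathrm{CA}) > 0.9$. The published marker
  list enumerates 37 names under a "36 biomarkers" count; we drop the
  granulocyte aggregate, whose components (neutrophils, basophils,
  eosinophils) are listed separately.
* **The ground-truth effect** is injected through the *computed*
  standardized score (E-DII by default), so `beta_true` is exactly "years
  of Δage per 1 SD of score as the cohort realizes it". Two modes:
  `"mediated"` shifts the inflammation-responsive biomarkers so each looks
  `beta_true` years older per score SD and lets the clock mediate the
  association (the clock attenuates the realized coefficient — by design,
  as in real pipelines); `"direct"` generates Δage itself, for testing the
  inference machinery in isolation, as
  $\Delta = -0.77 - 0.446\,(\mathrm{age} - 55.6) + \beta\,S +
  \varepsilon,\ \varepsilon \sim N(0, 5.71^2)$.
  The slope and residual SD are *derived*, not free: printed SDs of CA
  (11.6), BA (8.6) and Δage (7.7) jointly imply
  $\mathrm{corr}(\mathrm{BA},\mathrm{CA}) = 0.75$, a Δage-on-age slope of
  $-0.446$ and an age-conditional residual SD of 5.71 y. An optional
  sex-specific increment (`interaction_sex`) creates effect modification
  for power studies.

Not emulated: item-level FFQ structure (the real instrument has 188
items), real biomarker distributions, between-marker correlations beyond
the shared age/sex/diet factors, non-MCAR missingness mechanisms, and any
real-cohort coefficient values. Passing tests therefore demonstrate that
the *machinery* is correct and calibrated under a structurally faithful
generative model — not that real-data coefficients are reproduced; those
depend on restricted data.

## 6. Monte-Carlo calibration and problem sizes

The test suite runs, among others: parameter recovery at $\beta = 0.25$,
$n = 2000$, 200 replicates with default missingness and $m = 10$
(bias and 95% CI coverage); the same at $\beta \in \{0, 0.5\}$ with
zero missingness (where pooling equals the single fit exactly); 500-replicate
type-I-error calibration of the sex-interaction test at $n = 1500$; a
200-replicate power study at $n = 5000$; and a clock run at
$n = 10{,}000$ against an ordinary-least-squares oracle on the identical
split. These sizes keep the full suite within minutes on one CPU while
leaving Monte-Carlo error well below the tolerances tested.

One calibration consequence is worth stating plainly: with the derived
residual SD of 5.71 y, the analytic power of the two-sided 0.05-level Wald
test for a sex-interaction contrast of 0.5 y/SD at $n = 5000$ is about
0.86–0.89 (the contrast's SE is ≈ 0.16), so a ≥ 0.90 power expectation for
that scenario is not attainable under this noise calibration — the
corresponding check documents this rather than quietly lowering the noise.

## 7. Numerical choices and degenerate inputs

* Centered proportions use `pnorm` directly; no series approximations.
* `standardize_scores()` refuses constant input; `quartile_assign()`
  needs ≥ 4 values, warns and returns a single group when all values tie.
* Posterior draws in imputation use a small ridge ($10^{-8}$) before
  Cholesky factorization; rank-deficient imputation designs are pivoted
  down to their full-rank column set.
* Degenerate imputation cells (all observed values of a binary variable
  identical) fall back to the observed constant.
* The interaction $D_1$ statistic switches to its $\chi^2/k$ limit when
  the between-imputation variance is numerically zero.
* Seeds: every stage derives its own 32-bit seed from the root seed and a
  stage label, so stages are decoupled and everything replays exactly;
  user RNG state is saved and restored around every stochastic call.

## 8. Known limitations

* The clock is a small MLP, not a deep architecture; on strongly
  non-linear biomarker-age relationships it would understate what a
  deeper model could learn (the synthetic generator is affine, so this
  does not bind here).
* The lean imputation engine is tailored to covariate MCAR; under
  missingness that depends on unobserved covariate values its draws are
  not proper.
* Mediated-mode `beta_true` is the biomarker-level injection scale; the
  realized Δage coefficient is attenuated by the clock and is *not*
  calibrated to equal `beta_true` (the direct mode exists precisely to
  test calibrated recovery).
* The synthetic registries are placeholders with the right shape, not the
  proprietary reference values; scores computed from them are
  structurally, not numerically, comparable to published scores.
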
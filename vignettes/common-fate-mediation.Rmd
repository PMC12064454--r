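---
title: "Multilevel common fate mediation for dyadic diary data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel common fate mediation for dyadic diary data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In couples where one partner lives with a chronic condition such as HIV, many
daily experiences are genuinely shared: appraising the illness as "our"
problem (we-disease appraisal, WDA), coping with it together (common dyadic
coping, CDC), and the satisfaction both partners draw from the relationship.
The *common fate model* treats such constructs as dyad-level latent variables
measured by both partners' reports, in contrast to actor-partner models that
route effects through individual-level variables.

`commonfate` implements a 1-1-1 multilevel mediation analysis under this
model for intensive longitudinal (daily diary) designs: on each of `T` days,
both members of `J` couples rate WDA (0-6), CDC (0-30), quality of life
(QoL, 0-6) and relationship satisfaction (RS, 0-6); after the diary period
each couple contributes one post-diary record (WHO quality-of-life totals,
ART adherence days, PrEP attitude, a relationship-satisfaction inventory).
The mediation hypothesis is

> shared appraisal (WDA) -> shared coping (CDC) -> outcome,

decomposed into a *within-couple* level (day-to-day fluctuation around a
couple's own average; paths `a_w`, `b_w`, direct `c_w`) and a
*between-couple* level (stable differences between couples; `a_b`, `b_b`,
`c_b`). The indirect effect at each level is the product `a * b`.

## The model

Each level carries a structural equation system in reticular-action form.
At the within level, both partners' daily WDA reports load on a shared
latent (loadings fixed to 1), which predicts a shared CDC latent, which in
turn predicts the outcome; at the between level the same graph applies to
the couple-level components, and post-diary outcomes (measured once per
couple) attach there only. For observed daily indicators `y_jt` of couple
`j` on day `t` and between-only variables `z_j`,

```
y_jt = mu + Lambda_B eta_Bj + eps_Bj + Lambda_W eta_Wjt + eps_Wjt
z_j  = mu_z + f(eta_Bj) + eps_zj
```

with level-specific implied covariances
`Sigma_L = F (I - A_L)^-1 S_L (I - A_L)^-T F'`. The covariance of the
stacked data of one couple is exchangeable over days,
`I (x) Sigma_W + J (x) Sigma_B`, bordered by the between-only block. The
log-likelihood is evaluated through the eigenstructure of the exchangeable
part — `n_j - 1` deviation components with covariance `Sigma_W` and the
cluster mean jointly with `z_j` — so the dense `n_j p` covariance is never
materialized. A dense-covariance evaluation exists in the test suite as an
independent oracle.

Six outcome models are supported (`cfm_outcomes()`): daily QoL (two
partner-specific observed outcomes — QoL is deliberately *not* a common
fate construct), post-diary QoL, ART adherence (binary, >28 of 30 days),
PrEP attitude, daily RS (a shared latent outcome), and post-diary RS.

### Identification and estimation choices

* **Loadings fixed at 1, latent variances free.** This is the classic
  common fate parameterization. Partner-asymmetric *standardized* loadings
  (the typical empirical pattern) then arise from unequal residual
  variances, not from free loadings.
* **Latent within/between decomposition.** The two-level likelihood does
  the decomposition implicitly; no manual cluster-mean centering enters the
  estimator (centering is used only in the *descriptive* within/between
  correlations, where it is the conventional choice).
* **Day-level full-information ML.** A couple contributes every day on
  which all required indicators from both partners are present; days with
  any missing item are dropped for that couple, couples with no complete
  day are dropped with a logged count. This captures the dominant
  missingness mechanism of diary designs (skipped person-days) without
  pattern explosion, and is consistent under MCAR, which is also what the
  synthetic generator produces.
* **Optimization.** Quasi-Newton (bounded `nlminb`) on an unconstrained
  reparameterization — log variances, raw paths — started from moment-based
  values (grand means; paths at zero; latent variances at half the
  corresponding indicator-level variance), followed by Newton refinement on
  the numerically differentiated observed information until the gradient
  max-norm falls below `1e-5`. Bounds of `exp(+-18)` on variances keep the
  line search away from numerically degenerate regions. The optimizer is
  deterministic: refitting the same data reproduces estimates to machine
  precision.
* **Standard errors** come from the inverse observed information (central
  finite differences on the transformed scale, delta-method back-transform);
  test statistics are Wald z. The joint covariance of `(a, b)` used for
  mediation inference is the corresponding submatrix — *not* an independence
  assumption, which is a known source of bias for product confidence
  intervals.
* **Binary adherence** is treated as a linear model on the 0/1 indicator,
  and its fit indices are suppressed. The product-of-paths arithmetic is
  unaffected; a probit/logistic link is out of scope.

### Fit indices

The chi-square compares the fitted model with an ML fit of the two-level
*saturated* model (unrestricted `Sigma_W`, `Sigma_B`, means; Cholesky
parameterized so positive definiteness holds throughout); the baseline for
CFI/TLI is the two-level independence model. RMSEA uses `N =` total
person-days, recorded in the fit metadata so another convention can be
applied post hoc. SRMR is computed per level from standardized residuals
between the saturated-ML and model-implied moments. With `df = 0`, RMSEA
and TLI are reported as not applicable.

### Monte Carlo intervals for the indirect effect

`monte_carlo_ci()` draws `(a*, b*)` from the bivariate normal centered at
the estimates with the fitted joint covariance and takes empirical
percentiles of `a* b*`. Defaults: 20,000 draws, a mandatory seed, 95%
confidence. The point estimate is exactly `a * b`; the delta-method SE is
reported alongside. A quadrature evaluation of the exact product-normal
distribution serves as the oracle in the tests.

## The synthetic-data generator

Real data of this design are typically available only on request, so the
package ships a generator that *is* the model read forward, calibrated once
to a reference study profile (`study_profile()`): 141 couples, 14 days,
daily 7-point items, 4.4% of person-day records missing completely at
random, 14.9% ART-adherent, and the marginal means/SDs/ICCs and structural
paths of that profile (e.g. `a_w = 4.78`, `a_b = 2.08`, WDA ICC 0.83).
Residual variances are *solved* from the profile's SDs, ICCs and
standardized loadings given the paths; the calibration is internally
consistent (the implied standardized paths reproduce the profiled ones).

What the generator emulates — and does not:

* Scores are continuous (latent-normal) by default, matching the
  estimator's assumption; `likert = TRUE` rounds and clips to the integer
  scales as a robustness option, not the base case.
* Missingness is person-day MCAR. No MAR/MNAR mechanisms, and no
  day-to-day autoregression — the fitted model has none either, so passing
  tests say nothing about dynamics or informative missingness in real data.
* ART adherence days are drawn as `30 - min(Poisson(lambda), 30)` with
  `lambda` solved so the >28-day fraction matches its target; they are
  independent of the latents. This matches the marginal without inventing
  a structural claim (the reference profile's adherence paths are null).
* Cross-partner *residual* correlations are zero; the between-level
  correlation of the two partners' QoL implied by the structural paths is
  therefore smaller than the raw cross-partner correlations a real study
  may show. The generator targets ICCs and paths, not every bivariate
  descriptive.

## Known limitations, numerical notes

* ML variance estimates are biased in finite samples. At the reference
  size (141 couples), simulation shows between-level variance components
  (the CDC disturbance, QoL between residuals) estimated 4-10% low on
  average, vanishing by J = 1000. This is the ordinary ML-versus-REML
  effect, inherited by any plain-ML multilevel SEM; structural paths and
  the indirect effects built from them are unaffected to within Monte
  Carlo resolution.
* Variance estimates near zero are reported with a boundary warning; the
  log parameterization keeps them positive rather than truncating.
* Monotone progress: the reported maximum always dominates both the
  starting value and the generating-truth likelihood in the tests.
* No sandwich/robust or Bayesian variants, no WLSMV, no random slopes, no
  moderated mediation, no bootstrap intervals.

Problem sizes in the test suite were chosen to make the statistical checks
informative at the reference design: 200 replicates for parameter-recovery
checks of the daily QoL and daily RS models, 500 replicates for interval
coverage, and panels of 2,000-5,000 dyads for moment-consistency checks.

## A worked run

```{r, eval = FALSE}
library(commonfate)

gp  <- cfm_gen_params()                  # the reference study conditions
sim <- generate_panel(gp, seed = 1)

describe_panel(sim$panel, sim$post, n_dyads = 141, n_days = 14)

fit <- cfm_fit(cfm_model("daily_qol"), sim$panel)
fit

mediate(fit, "within",  "qol_PLWH", reps = 20000, seed = 1)
mediate(fit, "between", "qol_PLWH", reps = 20000, seed = 1)
```

The same pipeline is scriptable through config files
(`run_simulate()`, `run_fit()`, `run_mediate()`, `run_describe()`) or the
thin command-line dispatcher installed at
`system.file("cli", "cfm.R", package = "commonfate")`.
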
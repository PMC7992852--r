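---
title: "Scoring the Activity-Sleep Index and estimating mediated intervention effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the Activity-Sleep Index and estimating mediated intervention effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asimed)
```

## The scientific problem

Physical activity and sleep jointly influence mental health, but most
intervention studies analyse one behaviour at a time. When a trial targets
both, a natural question is whether its effect on mental-health outcomes is
*mediated* by the change in the overall activity-sleep behaviour pattern.
`asimed` implements the full analysis chain for that question in pooled
two-arm RCT data: a composite Activity-Sleep Index (ASI) that summarises
twelve behaviour dimensions on one scale, and a covariate-adjusted
single-mediator path analysis with bias-corrected bootstrap inference and
full-information maximum likelihood (FIML) for follow-up attrition.

## The Activity-Sleep Index

Twelve dimensions are scored: six for physical activity (MVPA session
frequency, resistance-training frequency, the vigorous fraction of MVPA,
activity type, MVPA weekly minutes, daily sitting minutes) and six for sleep
health (daytime alertness, overall sleep-quality rating, sleep timing, sleep
regularity, sleep efficiency, meeting the 7-9 h adult duration guideline).
Each raw dimension $X$ is min-max rescaled to $[0, n]$ with $n = 10$:

$$\text{score} = \frac{X - X_{\min}}{X_{\max} - X_{\min}} \, n,$$

where the bounds are the observed minimum and maximum pooled **over all
assessment points and both arms**, frozen before any scoring call
(`compute_bounds()`), so every wave and arm shares one scale. Dimensions
where a higher raw value is higher-risk (sitting, daytime sleepiness, worse
quality rating, more variable bed/wake times) are reflected to $n -
\text{score}$, so high scores always mean lower-risk behaviour. The ASI-12
is the sum over all twelve dimensions (0-120); the ASI-6 short form keeps
resistance training, MVPA duration, sitting, sleep quality, sleep efficiency
and sleep duration (0-60) for studies with sparser instruments.

Design choices that were genuinely open:

* **Sleep timing** is scored as a binary low-risk indicator (midpoint of
  sleep between 02:00 and 04:00) *before* rescaling; published group means
  for this dimension are consistent with a near-binary score. A graded
  distance-from-window variant sits behind `asi_dimensions(timing =
  "graded")`.
* **Sleep duration** uses the 7-9 h adult guideline as a binary indicator;
  the band is configurable (`duration_range`) because guidelines are
  age-specific outside the 18-64 range the design targets.
* **MVPA minutes** are truncated at 840 min/wk (the activity-questionnaire
  convention) before scoring so that a single extreme recall cannot stretch
  the pooled bounds for everyone; configurable via `mvpa_cap`.
* **Partially missing profiles** score as missing (no pro-rating): a
  pro-rated composite would quietly change meaning across waves.
* **Degenerate bounds** (a dimension constant in the data) score $n/2$ with
  a loud warning; the dimension then carries no information and any constant
  is arbitrary, but $n/2$ keeps the composite's range symmetric.
* Bounds are pooled across the two trials by default (matching the pooled
  analysis); per-trial bounds can be had by scoring trials separately.

## The mediation model

For mediator $M$ (ASI-12 or ASI-6), outcome $Y$, wave $w \in \{3, 6\}$
months, randomised arm $G$, and study indicator $S$ (two pooled trials), the
paths are estimated from three linear models:

* $a$: $M_w \sim G + M_0 + S$ — intervention effect on the mediator,
  adjusted for its baseline;
* $b$ and $c'$: $Y_w \sim G + M_w + M_0 + Y_0 + S$ — mediator-outcome
  association and direct effect, adjusted for baseline mediator and outcome
  (the default "footnote" convention; `covariates = "methods"` drops $M_0$,
  and `covariates = "matched"` uses the identical covariate set in all three
  models, which makes $c = c' + ab$ an exact algebraic identity);
* $c$: $Y_w \sim G + Y_0 + S$ — total effect.

The mediated effect is the product of coefficients $ab$, and the proportion
mediated is $100\,ab/c$ (suppressed when $|c| < 10^{-8}$, where the ratio is
meaningless; sign inconsistency between $ab$ and $c$ is flagged). The
no-interaction assumption is checked by adding a $G \times M_w$ term to the
outcome model (`interaction_check()`).

### Bias-corrected bootstrap

The 95% CI for $ab$ resamples whole participants with replacement — both
trials pooled, no stratification, because the analysis pools and adjusts for
study — $B = 5000$ times by default. With $\hat{ab}$ the point estimate and
$ab^*_1, \dots, ab^*_B$ the resampled products, the bias-correction constant
is $z_0 = \Phi^{-1}(\#\{ab^* < \hat{ab}\}/B)$ (ties counted half below), and
the interval endpoints are the empirical quantiles of the $ab^*$ at
$\Phi(2z_0 \pm z_{0.975})$. No acceleration constant is used (BC, not BCa).
Quantiles follow the type-6 rule, matching common commercial SEM software;
other conventions can move an endpoint in its last decimal. Degenerate
resampling distributions return a degenerate interval with a warning, and a
$z_0$ of $\pm\infty$ (every resample on one side) is an error advising a
larger $B$.

### FIML for follow-up attrition

Conditional on the complete exogenous covariates, the follow-up pair
$(M_w, Y_w)$ is bivariate normal under the path model; `fiml_fit()`
maximises the observed-data log-likelihood in which each missingness
pattern contributes its marginal normal density. This keeps participants
with, say, an observed outcome but a missing mediator in the likelihood.
Numerical choices: quasi-Newton (BFGS) from complete-case starting values
with analytic gradients, relative log-likelihood tolerance $10^{-10}$,
followed by Newton polishing steps on the analytic gradient until the
gradient norm is below $10^{-9}$ — with complete data the optimum then
matches OLS to near machine precision, which the tests assert. Standard
errors come from the inverse observed information.

Two structural facts discovered while validating, worth knowing when
choosing covariate sets:

* When the mediator-equation covariates are a subset of the outcome-equation
  covariates (the "footnote" default), partial missingness patterns carry
  essentially no information about $b$: the implied marginal mean of the
  outcome is collinear with the outcome-equation coefficients, so FIML and
  complete-case OLS are asymptotically equivalent for $b$.
* Under the "methods" variant the baseline mediator is excluded from the
  outcome model (which matches the generator's causal structure, where the
  baseline mediator affects the outcome only through the follow-up
  mediator). It then acts as an exclusion-restriction auxiliary variable,
  and FIML is strictly more efficient than complete case when mediator
  values are missing at random given the baseline outcome — the
  configuration the acceptance checks exercise.

By default `mediate()` takes point estimates from FIML but bootstraps the
complete-case product (the two coincide exactly on complete data); a full
FIML bootstrap is available with `boot_engine = "fiml"` at roughly a
hundred-fold cost.

## What the synthetic cohort emulates

`simulate_cohort()` generates the pooled two-trial design the package
targets: trial A randomises 80/80 (adults 18-55, age mean 41.5, SD 9.9),
trial B 110/55 (adults 45-64, age mean 52.0, SD 6.9) — 190 intervention and
135 control in total, 81.2% female. Baseline outcome scales use the pooled
baseline means and SDs (e.g. depression 10.7 (8.1) on the doubled 0-42
scale) truncated to instrument ranges.

Behaviour is generated on raw scales and pushed through the real scoring
path. Continuous dimensions are truncated normals on fixed supports with a
Gaussian copula giving correlation 0.5 between consecutive waves; ordinal
dimensions are drawn from fixed category distributions. The intervention
effect `a_true` (default 3 ASI-12 points, matching the fitted a-paths the
design targets) is induced by shifting the pre-truncation means of four
continuous dimensions — MVPA sessions, MVPA minutes, sitting (down), sleep
efficiency — with each raw shift solved numerically so the post-truncation
mean moves by exactly $(a_\text{true}/4) \times E[\text{observed
range}]/10$. Because scoring rescales by the *observed* pooled bounds, the
expected observed range at the configured sample size (an order-statistic
quantile approximation of the mixture of shifted and unshifted draws,
iterated to a fixed point) is used rather than the support width; across
200 replicates at n = 5000 the recovered $\hat a$ is unbiased to within
Monte-Carlo error.

Follow-up outcomes are linear-Gaussian in the scored mediator:
$$Y_w = \mu + c'_\text{true} G + b_\text{true}(M_w - m_\text{ref}) +
\gamma (Y_\text{prev} - \mu) + \delta S + \varepsilon,$$
with $\gamma = 0.5$ carryover ($Y_\text{prev}$ is baseline at wave 3 and
the wave-3 value at wave 6) and per-outcome residual SDs chosen to keep
follow-up variances near baseline ones. Default `b_true` and `cprime_true`
mirror the per-outcome magnitudes the design targets (e.g. depression
$-0.10$ per ASI unit). Two deliberate deviations from strict realism:

* Follow-up outcomes are *not* clipped to instrument ranges — clipping
  would bias the very estimators the generator exists to validate. A few
  tenths of a percent of simulated depression scores fall slightly below
  zero; analysis functions band such values at the instrument floor.
* Ordinal dimensions carry no intervention effect, so the whole `a_true`
  loads on four continuous dimensions. Real trials also move
  resistance-training frequency and quality ratings; the composite-level
  behaviour is the same, the per-dimension decomposition is not.

Attrition is missing at random: each follow-up is deleted with probability
$\text{logit}^{-1}(\beta_0 + \beta_\text{age}(\text{age} - 47) +
\beta_{y}(Y_0 - \bar Y_0))$, defaults $\beta_\text{age} = -0.05$/yr and
$\beta_y = 0.04$ per depression unit — younger, more symptomatic
participants drop out more, the pattern observed in the source trials. The
intercepts are calibrated (`calibrate_missingness()`) so expected completion
is 84.9% at 3 months and 65.5% at 6 months; dropout is monotone by default.
The strength of the age and baseline-outcome dependence is illustrative,
not estimated from the trials, which publish no such coefficients. A
`scope` option deletes the whole wave (survey attrition, default) or only
the mediator or outcome block (instrument-level skipping), the latter being
what makes FIML and complete case genuinely differ.

What passing tests on this generator do **not** show about real data:
behaviour distributions are stylised (no zero-inflation in MVPA, no digit
preference, no seasonal trends), control-arm scores have no secular
improvement, outcomes are conditionally Gaussian, and missingness follows
the exact logistic model the estimator assumes. Results on real cohorts
inherit none of these guarantees.

## Descriptive layer

`cohens_d()` uses the pooled-SD convention, intervention minus control,
with the standard large-sample variance for its CI (the CI convention of
the source tables is unknown, so only the point estimate is treated as
reproducible). DASS-21 severity bands live in an editable JSON resource
(doubled-scale cutpoints: depression 10/14/21/28, anxiety 8/10/15/20,
stress 15/19/26/34, closed on the left); published baseline category
tables are consistent with doubled scores, and a `doubled = FALSE` switch
halves the cutpoints. Improvement is any reduction of at least one band.
Completer/non-completer comparisons use independent t-tests and chi-square
tests without continuity correction.

## Problem sizes used in the validation suite

The shipped checks use: 50 replicate cohorts at n = 325 for the exact
decomposition identity; 200 replicates at n = 325 with B = 500 for null
calibration and coverage of the BC interval; 200 replicates at n = 5000 for
parameter recovery; and 200 paired replicates at n = 650 for the
FIML-versus-complete-case comparison. These sizes give Monte-Carlo standard
errors comfortably inside the asserted tolerances while keeping a full run
of the suite around a minute of compute.

## Known limitations

* Single mediator only: no serial or multiple mediation, no latent
  variables, no moderated mediation beyond the interaction check, and no
  per-dimension mediation (the composite is the unit of analysis).
* The BC interval is bias-corrected but not accelerated; for strongly
  skewed resampling distributions BCa can differ.
* FIML assumes conditional normality of the follow-up pair; gross
  non-normality of residuals transfers to its likelihood.
* The proportion mediated is unstable whenever the total effect is near
  zero — it is reported with a floor and a sign-consistency flag, and
  should be read descriptively.
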
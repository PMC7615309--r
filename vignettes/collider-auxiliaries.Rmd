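---
title: "Collider auxiliaries in multiple imputation: models, formulas and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collider auxiliaries in multiple imputation: models, formulas and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colliderMI)
```

This vignette is the package's own account of the science it implements:
the structural model, the closed-form bias and standard-error results,
the Monte-Carlo designs, and the judgement calls made where the design
was genuinely open.

## The structural model

Every scenario is a linear-Gaussian path model: a DAG over named
variables in which each variable equals an intercept plus a linear
combination of its parents plus an independent Gaussian error. The
canonical outcome-missing scenario (`path_model_preset("fig1")`) has
outcome $Y$, exposure $X$, direct predictor $Z$, collider $W$, an
unmeasured variable $U$, and a latent normal missingness variable $R$:

$$Y = \beta_{YX} X + \beta_{YZ} Z + e_Y,\qquad
  W = \beta_{WZ} Z + \beta_{WU} U + e_W,\qquad
  R = \beta_{RX} X + \beta_{RU} U + e_R.$$

$Y$ is observed if and only if $R \le r$, so the observation indicator
follows a probit model and the missingness proportion is
$\pi_0 = P(R > r)$. $W$ is a *collider* of $Y$ and its missingness: it
shares the cause $Z$ with $Y$ and the cause $U$ with $R$. Missingness is
MAR given $X$, so complete-records analysis (CRA) and MI with $X$ alone
are both valid; the question is what happens when the imputation model
for $Y$ also uses $W$ (and not $Z$).

Implied moments are computed exactly by the reduced form: with
coefficient matrix $B$ and error covariance $\Psi$,
$\Sigma = (I-B)^{-1}\Psi(I-B)^{-\top}$. We deliberately avoid estimating
these by simulation: the downstream bias formulas take ratios of small
covariance products, where Monte-Carlo error would dominate. Positive
semi-definiteness is accepted down to a relative eigenvalue of
$-10^{-10}$ (floating-point slack); the variable ordering is the
topological order with ties broken by declaration, so results are
deterministic for a given specification.

## Bias of the MI estimator

With $X$ and $W$ (but not $Z$) in the imputation model, the MI estimator
of $\beta_{YX}$ converges, as the number of imputations grows, to
$\alpha_1^{\mathrm{OBS}}$ — the coefficient on $X$ in the imputation
model fitted to complete records. Its bias rises from 0 at $\pi_0 = 0$
to $|\beta_{YX|W,R} - \beta_{YX}|$ as $\pi_0 \to 1$, the conditioning
route implemented in `bias_bound()`. The equivalent direct-effects form
(`max_bias_outcome()`) is

$$\frac{\beta_{RX}\beta_{RU}\beta_{WU}\beta_{YZ}\beta_{WZ}\,
        \sigma^2_Z\sigma^2_U}
       {(\beta^2_{RU}\sigma^2_U+\sigma^2_R)
        (\beta^2_{WZ}\sigma^2_Z+\sigma^2_W)
        +\beta^2_{WU}\sigma^2_U\sigma^2_R}.$$

Three structural properties follow and are enforced as randomized
property tests: the value is independent of $\beta_{YX}$, its sign is
the sign of the five-coefficient product, and it is exactly zero when
any one of those five paths is absent. The two routes must agree to
$10^{-8}$ over randomized models (coefficients in $[-2,2]$, error
variances in $[0.25,4]$).

Between the endpoints the bias grows *approximately* linearly in
$\pi_0$, because the map from the binary indicator to the underlying
normal is approximately linear. The approximation degrades near
$\pi_0 = 1$: at $\pi_0 = 0.9$ in the all-ones scenario the true value is
about 0.149 (not the linear extrapolation 0.18), computed independently
by a single very large complete-records regression below the latent-$R$
quantile; our simulation tests assert against that reference, not
against exact linearity.

When the *exposure* is partially observed instead
(`path_model_preset("fig4")`), the imputation and analysis models no
longer coincide; `max_bias_exposure_alpha1()` implements the maximum
bias of the imputation-model coefficient on $Y$,

$$\frac{A\{\mathrm{Var}(Y)\,\mathrm{Cov}(Y,X|W)
        -\mathrm{Cov}(Y,X)\,\mathrm{Var}(Y|W)\}}
       {\mathrm{Var}(Y|W)\{\mathrm{Var}(Y|W)-A\,\mathrm{Var}(Y)\}},
  \qquad A=\frac{\mathrm{Cov}^2(R,W)}{\mathrm{Var}(R)\mathrm{Var}(W)},$$

and the induced bias in the MI estimate of $\beta_{YX}$ is small (there
is only one biasing pathway). Adding an edge $Y \to R$
(`"fig6"`) restores a second pathway; CRA then becomes invalid and the
MI-with-collider bias returns to the outcome-case order of magnitude —
both shown by simulation, as no closed form is derived for that case.

## Standard errors

`se_profile()` returns the endpoint standard errors for $n$ observed
records. At $\pi_0=0$ the MI estimator has the collider-adjusted SE
$\sqrt{(\mathrm{Var}(Y)-\beta_{YX}^2\mathrm{Var}(X)
-\mathrm{Cov}^2(Y,W)/\mathrm{Var}(W))/(n\mathrm{Var}(X))}$ and CRA the
unadjusted analogue; as $\pi_0\to1$ they tend to
$\sqrt{\mathrm{Var}(Y|X,W,R)/(n\,\mathrm{Var}(X|W,R))}$ and
$\sqrt{(\mathrm{Var}(Y)-\beta_{YX}^2\mathrm{Var}(X))/
(n\{\mathrm{Var}(X)-\mathrm{Cov}^2(X,R)/\mathrm{Var}(R)\})}$. The MI
limit is evaluated through conditional moments rather than the long
expanded quadratic form: the two are algebraically identical and the
conditional route is numerically stabler; the all-ones case is
unit-tested against hand-computed values
($0.0408 \to 0.0506$ for MI, $0.0447 \to 0.0548$ for CRA at $n=1000$).
`relative_precision()` is $100(1-\mathrm{SE}^2_{MI}/\mathrm{SE}^2_{CRA})$.

### Which "MI standard error"? {#which-se}

A genuinely open design point. The literal finite-$m$ pooled slope
carries two extra noise terms: the Rubin $B/m$ Monte-Carlo component,
and a collider-projection term — by OLS residual orthogonality the
pooled slope at $m\to\infty$ equals
$\hat\alpha_1 + \hat\alpha_2\,\widehat{\mathrm{Cov}}(X,W)/\widehat{\mathrm{Var}}(X)$,
whose second term is $O(n^{-1/2})$, i.e. *the same order as the SE
itself* and therefore never negligible relative to SE differences of a
percent. The algebraic results instead identify the MI estimator with
$\hat\alpha_1^{\mathrm{OBS}}$, whose SE runs exactly from the
collider-adjusted value to the $R$-conditional limit.
`find_se_crossover()` therefore defaults to the
$\hat\alpha_1^{\mathrm{OBS}}$ identification (`estimator = "alpha1"`),
under which the weakened-predictor scenario
($\beta_{YZ}=\beta_{WZ}=0.5$) crosses the CRA SE at roughly 40%
missingness; `estimator = "pooled"` gives the literal estimator, whose
crossing occurs much earlier because of the extra noise. Standard errors
per grid point are, by default, averages of model-based per-replicate
SEs (`se_method = "model"`), which track the empirical standard
deviations within about 1% here while carrying far less Monte-Carlo
noise; the crossing of the quadratically smoothed difference curve is
returned. The same identification explains why the pooled estimate and
$\hat\alpha_1^{\mathrm{OBS}}$ agree closely *in expectation* (their
per-setting means differ by well under 0.001 in the test suite) while
individual datasets can differ by the order of one standard error.

## The MI engine

`impute_normal()` is proper Bayesian normal-linear imputation under the
noninformative prior: residual variance drawn from its scaled
inverse-$\chi^2$ posterior, coefficients from their Gaussian posterior
given that draw, imputations as linear predictor plus noise. Proper
draws are what make the Rubin's-rules total variance
$T = W + (1+1/m)B$ calibrated; the test suite checks 95% interval
coverage within $[0.92, 0.98]$ over 600 valid-MAR replicates. Degrees of
freedom use the classical rule $(m-1)(1+W/((1+1/m)B))^2$ (the source
results do not state a rule; the classical one is documented and used
throughout, with $B=0$ mapped to $\infty$). Imputing a variable with no
missing entries is an *error*, not a no-op: silent no-ops mask pipeline
bugs. A Bayesian-logistic binary imputer (`impute_binary()`) is included
for the binary extension and flagged experimental, since the
latent-normal argument transfers the continuous results only
approximately. Default $m$ is 100, large enough that pooled estimates
and SEs are stable.

## The simulator

`simulate_complete()` draws each variable from its structural equation
in topological order, with one child RNG stream per variable derived
from the dataset seed and the variable name — adding a downstream
variable therefore never perturbs upstream draws, which keeps scenario
comparisons paired. `impose_missingness()` thresholds the latent $R$:
theoretical calibration sets $r = \mu_R + \sqrt{V_R}\,\Phi^{-1}(1-\pi_0)$
so $\pi_0$ is exact in expectation; empirical calibration uses the
realized quantile, fixing the observed count exactly (the Monte-Carlo
harness uses the empirical mode so every replicate has the same number
of observed records). Binary variables are produced by latent-normal
thresholding (`dichotomize()`), not by logistic sampling, matching the
underlying-normal argument; downstream variables are generated from the
latent continuous value. A warning is emitted for prevalences within
0.01 of the boundary, where that correspondence degrades. Latent columns
($U$, $R$) are kept in the table for diagnostics but flagged, and every
estimator in the package takes an explicit predictor list, so they can
never leak in silently.

## The synthetic cohort generator

`make_alspac_like()` emulates the applied example's structure: binary
exposure `mated` (maternal post-16 education, prevalence 0.64, binomial
variance 0.230), binary `pregsize` (twin birth, prevalence 0.026),
collider `bwt` (birth weight in kg: intercept 3.42, +0.05 for maternal
education, −0.91 for twins, SD ≈ 0.53 so Var ≈ 0.286), outcome `bmi7`
(BMI at age 7 in kg/m²: intercept 16.1, −0.11 for maternal education,
−0.45 for twins, residual SD 2), a standard-normal latent $U$, and 40%
missing outcomes with education and $U$ driving observation
(the education log odds ratio for an observed outcome is ≈ 0.81,
odds ratio ≈ 2.3). $U$ loads on `bwt` (0.30), on missingness (−0.40)
*and directly on `bmi7`* (0.60): the last path makes $U$ an unmeasured
confounder of the outcome–collider relationship and the outcome mildly
MNAR. That choice mirrors the applied setting — where adjusting for the
direct predictor did not remove the collider bias and the observed
attenuation exceeded the plug-in formula value — and gives the fixture a
collider attenuation (≈ 0.01–0.03 across seeds at $n = 12{,}061$) that
is detectable in a single dataset. The generator reproduces this
qualitative regime, not any real cohort's microdata; it contains no
measurement error, no nonlinearities, and a single latent confounder, so
passing tests demonstrate correct behaviour *under the stated structural
model*, not robustness to the full messiness of real cohort data.

## Monte-Carlo designs

`sweep_pi0()` follows the fixed-observed-count convention: the number of
observed records is held at `n_obs` and total rows are inflated to
`n_obs/(1-π₀)`. This matters — holding the total fixed instead changes
every SE curve — and is stated here prominently. Analytic overlay
columns depend only on the model, never on the replicates (tested).
`sweep_effects()` evaluates the closed forms over coefficient grids,
optionally adding simulated bias at fixed $\pi_0$; the grid cells over
the unmeasured-cause paths are retained so they can be marginalized into
box plots. Test and acceptance runs use desk scales — typically 300–1000
replicates, $m = 10$–$20$, 1000 observed records — chosen so the whole
suite completes in minutes while Monte-Carlo standard errors (quoted as
$4\times$MCSE in assertions) remain well below the effects being tested.

## The applied two-step workflow

`screen_auxiliaries()` fits a regression per ordered pair — logistic for
binary dependents, linear otherwise — with the variables preceding the
explanatory one as the adjustment set. The causal ordering is *declared
by the user*, never inferred: deciding which way an association runs is
a substantive judgement the tool must not automate. The collider flag
requires the auxiliary–indicator association to strengthen by at least
half a standard error of the conditional estimate when the candidate
collider is conditioned on; without a margin, two noisy near-null
estimates would raise flags at random.

`estimate_summary_stats()` uses the stated estimation conventions:
binomial variance for a binary exposure, collider variance from all
records, outcome–collider covariance from complete records, exposure log
odds ratio marginal, collider log odds ratio adjusted for the exposure.
The covariance form is written for a *marginal* collider–$R$ covariance;
substituting the adjusted estimate follows applied practice, and every
`plugin_bias` report carries a note recording that substitution.
`plugin_max_bias()` adds the approximate interval
$\text{max bias} \pm 1.96 \times \text{SE}$, the multiplier
configurable; the direction note ("towards the null") compares the sign
of the bias against the sign of the analysis estimate. The covariance
form has a validity boundary: for implied $\mathrm{Cov}(X,R)$ or
$\mathrm{Cov}(W,R)$ large enough to make the denominator non-positive,
the function raises an explanatory error rather than returning a signed
infinity. The logit→probit constant 0.6 is a named default, overridable
per `summary_stats()`, and is itself an approximation that fails when
the proportion of complete records is very close to 0 or 1.

## Known limitations

Only one variable is ever missing; chained equations for multiple
incomplete variables, predictive mean matching, MNAR sensitivity
analyses, interactions and nonlinear structural equations are out of
scope. The closed forms assume joint normality with linear effects;
binary-variable results transfer only via the latent-normal
approximation. The plug-in formula treats its summary inputs as known:
its interval reflects only the reference SE, not uncertainty in the
variances, covariances and odds ratios, and its value is a *maximum*
(attained as $\pi_0 \to 1$), so real attenuations can exceed it when the
structural model is incomplete — exactly what the unmeasured-confounder
path in the synthetic cohort generator illustrates.
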
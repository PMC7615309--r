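# colliderMI

Quantifying the bias and precision cost of using a **collider** as an
auxiliary variable in multiple imputation (MI).

## The problem

Epidemiological analyses routinely impute missing values with MI and add
*auxiliary variables* — variables outside the analysis model — to the
imputation model, to sharpen the imputations and make the
missing-at-random (MAR) assumption more plausible. But an auxiliary
variable that shares one unmeasured common cause with the partially
observed variable and another with its missingness is a **collider**:
conditioning on it inside the imputation model opens an M-shaped biasing
path and *induces* a missing-not-at-random mechanism. The MI estimate can
then be biased even though every model is correctly specified, and the
collider may inflate rather than reduce the standard error.

`colliderMI` is for analysts and methodologists who want to know, before
adding an auxiliary variable, *how bad it could be*: it computes the
maximum induced bias exactly for linear-Gaussian path models, profiles
the MI and complete-records (CRA) standard errors, reproduces the results
by simulation, and provides a two-step applied workflow (screen candidate
auxiliaries for collider signatures, then plug summary statistics into a
maximum-bias formula with an approximate confidence interval).

## The model and the central result

Scenarios are linear-Gaussian path models over outcome *Y*, exposure *X*,
direct predictor *Z*, collider *W*, unmeasured cause *U*, and a latent
normal variable *R* whose thresholding defines the observation indicator
(probit missingness): `Y` is observed iff `R ≤ r`, so the missingness
proportion is `π₀ = P(R > r)`. The analysis model is the regression of
*Y* on *X* with coefficient `β_YX`; the imputation model for *Y* uses *X*
and *W*.

The bias of the MI estimator of `β_YX` rises from 0 (no missing data)
towards a maximum (all data missing) of

```
            β_RX β_RU β_WU β_YZ β_WZ σ²_Z σ²_U
  ─────────────────────────────────────────────────────────
  (β²_RU σ²_U + σ²_R)(β²_WZ σ²_Z + σ²_W) + β²_WU σ²_U σ²_R
```

which equals `β_YX|W,R − β_YX|W` from Gaussian conditioning (both routes
are implemented and must agree). The magnitude does not depend on `β_YX`;
the sign is the sign of the five-coefficient product; the bias is exactly
zero when any one of those five paths is absent. For applied work the
equivalent covariance form

```
  Cov(X,R) Cov(W,R) Cov(Y,W)
  ─────────────────────────────────────────────── ,
  {Var(X) − Cov²(X,R)} Var(W) − Var(X) Cov²(W,R)
```

with `Cov(·,R) = 0.6 × logOR × Var(·)` recovered from logistic
regressions of the observation indicator (the logit→probit 0.6 rule),
takes only observable summary statistics. Companion formulas give the MI
and CRA standard errors at `π₀ = 0` and in the `π₀ → 1` limit, and the
package's Monte-Carlo harness fills in everything between.

## Worked example

The reference outcome-missing scenario with every path coefficient and
error variance equal to 1:

```r
library(colliderMI)
model <- path_model_preset("fig1")
max_bias_outcome(model)
#> [1] 0.2
se_profile(model, n_observed = 1000)
#> Collider-auxiliary bias/SE report (n observed = 1000 )
#>   bias in [0, 0.2] (sign +1)
#>   SE(MI)  : 0.04082 at pi0=0  ->  0.0506 as pi0->1
#>   SE(CRA) : 0.04472 at pi0=0  ->  0.05477 as pi0->1
#>   relative precision of MI vs CRA at the limit: 14.7%
```

So if the imputation model for `Y` includes the collider `W`, the MI
estimate of `β_YX = 1` can be off by up to 0.2 — a fifth of the true
effect — with the bias growing roughly linearly in the fraction of
missing outcomes, while the precision gain over CRA is at most ~15% here.

The applied two-step workflow on the bundled synthetic birth-cohort
generator (binary exposure `mated`, outcome `bmi7`, candidate auxiliaries
`pregsize` and birth weight `bwt`, 40% missing outcomes):

```r
d <- make_alspac_like(n = 12061, seed = 1)
sc <- screen_auxiliaries(d, c("mated", "pregsize", "bwt"))
sc$collider_checks
#>   auxiliary conditioned_on logor_unadjusted logor_conditional conditional_se strengthened
#> 1     mated       pregsize       0.81445242         0.8144207     0.03886110        FALSE
#> 2     mated            bwt       0.81445242         0.8067389     0.03930694        FALSE
#> 3  pregsize            bwt       0.02814615         0.5873662     0.12221370         TRUE
```

The `pregsize`–missingness association jumps from log-odds 0.03 to 0.59
once birth weight is conditioned on — the collider signature (Step 1).
Step 2 plugs the estimated summary statistics into the covariance form:

```r
ss <- estimate_summary_stats(d, c(outcome = "bmi7", exposure = "mated",
                                  collider = "bwt"))
cs <- compare_strategies(d, roles = c(outcome = "bmi7", exposure = "mated",
                                      predictor = "pregsize", collider = "bwt"),
                         m = 100, seed = 2)
plugin_max_bias(ss, se_reference = cs$se[cs$strategy == "MI+W"],
                estimate = cs$estimate[cs$strategy == "CRA"])
#> Plug-in maximum bias: 0.034 (95% CI -0.074 to 0.141)
#>   note: towards the null; collider log odds ratio estimated conditional on
#>   the exposure, substituted for the marginal covariance
```

and the strategy comparison shows the predicted attenuation when the
collider enters the imputation model:

```r
cs
#>  strategy   estimate         se
#>       CRA -0.2411013 0.05414915
#>        MI -0.2404379 0.05501526
#>      MI+Z -0.2443668 0.05502181
#>      MI+W -0.2142247 0.05479160
#>    MI+Z+W -0.2080707 0.05301093
```

MI with birth weight shifts the (negative) education effect towards the
null by ~0.03, in line with the plug-in bound, and adding `pregsize` does
not undo it.

With published summary statistics the plug-in formula can be evaluated
directly — e.g. observation odds ratios 2.31 (exposure) and 1.15
(collider), `Var(X) = 0.228`, `Var(W) = 0.286`, `Cov(Y,W) = 0.171` give a
maximum bias of 0.008.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "collidermi.R", package = "colliderMI")` with
subcommands `simulate`, `fixture`, `max-bias`, `se-profile`, `sweep-pi0`,
`sweep-effects`, `crossover`, `screen`, `plugin-bias` and `compare`.

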
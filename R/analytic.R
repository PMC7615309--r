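#' Maximum bias of the MI estimator with a collider in the imputation model
#' (partially observed outcome)
#'
#' Closed-form maximum bias of the MI estimator of the exposure coefficient
#' when the outcome `Y` is partially observed and the imputation model uses
#' the exposure `X` and the collider `W` (but not the direct predictor `Z`).
#' In terms of the direct effects `beta` and error variances `sigma^2`:
#'
#' \deqn{\frac{\beta_{RX}\beta_{RU}\beta_{WU}\beta_{YZ}\beta_{WZ}
#'   \sigma^2_Z \sigma^2_U}
#'   {(\beta_{RU}^2\sigma^2_U + \sigma^2_R)
#'    (\beta_{WZ}^2\sigma^2_Z + \sigma^2_W)
#'    + \beta_{WU}^2\sigma^2_U\sigma^2_R}}
#'
#' The magnitude does not depend on `beta_YX`; the sign equals the sign of
#' the product of the five coefficients in the numerator, and the value is
#' exactly zero whenever any one of them is zero. The bias of the MI
#' estimator at missingness proportion `pi0` lies between 0 (at `pi0 = 0`)
#' and this value in magnitude (as `pi0` tends to 1).
#'
#' @param model a [path_model()] with the outcome-missing (`"fig1"`) role
#'   structure: roles `outcome`, `exposure`, `predictor`, `collider`,
#'   `unmeasured` and `missingness` all present.
#' @return signed maximum bias (numeric scalar).
#' @seealso [bias_bound()] for the equivalent conditional-moments route,
#'   [max_bias_covform()] for the covariance form used with summary data.
#' @export
#' @examples
#' max_bias_outcome(path_model_preset("fig1"))  # 0.2
max_bias_outcome <- function(model) {
  stopifnot(inherits(model, "path_model"))
  Y <- role_var(model, "outcome"); X <- role_var(model, "exposure")
  Z <- role_var(model, "predictor"); W <- role_var(model, "collider")
  U <- role_var(model, "unmeasured"); R <- role_var(model, "missingness")
  if (path_coef(model, X, Z) != 0 || path_coef(model, R, Y) != 0) {
    stop("model does not have the outcome-missing (fig1) structure")
  }
  b_RX <- path_coef(model, R, X); b_RU <- path_coef(model, R, U)
  b_WU <- path_coef(model, W, U); b_YZ <- path_coef(model, Y, Z)
  b_WZ <- path_coef(model, W, Z)
  s2 <- model$error_variances
  num <- b_RX * b_RU * b_WU * b_YZ * b_WZ * s2[[Z]] * s2[[U]]
  den <- (b_RU^2 * s2[[U]] + s2[[R]]) * (b_WZ^2 * s2[[Z]] + s2[[W]]) +
    b_WU^2 * s2[[U]] * s2[[R]]
  num / den
}

#' Bias bound for the MI estimator via conditional moments
#'
#' The bias of the MI estimator of the exposure coefficient, with the
#' stated imputation predictors, is bounded between 0 and
#' `|beta_{YX|preds,R} - beta_{YX|preds}|`, where both population
#' coefficients are obtained by Gaussian conditioning on the implied joint
#' distribution (including the latent missingness variable `R`). For the
#' outcome-missing structure with predictors `{X, W}` this bound equals
#' [max_bias_outcome()] in magnitude.
#'
#' @inheritParams max_bias_outcome
#' @param imputation_predictors predictors of the imputation model;
#'   defaults to the exposure and the collider.
#' @return named numeric vector `c(lower = 0, upper = ...)`.
#' @export
#' @examples
#' bias_bound(path_model_preset("fig1"))  # c(0, 0.2)
bias_bound <- function(model, imputation_predictors = NULL) {
  stopifnot(inherits(model, "path_model"))
  Y <- role_var(model, "outcome"); R <- role_var(model, "missingness")
  if (is.null(imputation_predictors)) {
    imputation_predictors <- c(role_var(model, "exposure"),
                               role_var(model, "collider"))
  }
  if (length(bad <- setdiff(imputation_predictors, model$variables))) {
    stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  }
  X <- role_var(model, "exposure")
  if (!X %in% imputation_predictors) {
    stop("the imputation predictors must include the exposure")
  }
  joint <- implied_moments(model)
  b_with <- conditional_regression(joint, Y, c(imputation_predictors, R))
  b_without <- conditional_regression(joint, Y, imputation_predictors)
  c(lower = 0,
    upper = abs(unname(b_with$coefficients[X] - b_without$coefficients[X])))
}

#' Summary statistics for the covariance-form maximum bias
#'
#' Bundles the summary inputs of the applied plug-in formula. The latent
#' missingness variable `R` is standardized to mean 0 and variance 1;
#' covariances with `R` are recovered from the log odds ratios of logistic
#' regressions of the observation indicator via the probit conversion
#' `Cov(., R) = factor * logOR * Var(.)` with `factor = 0.6` by default.
#'
#' @param var_x,var_w marginal variances of the exposure and the collider
#'   (for a binary exposure use the binomial variance `p(1-p)`).
#' @param cov_yw covariance of outcome and collider (estimated on complete
#'   records in the applied workflow).
#' @param logor_x_r log odds ratio from the logistic regression of the
#'   observation indicator on the exposure.
#' @param logor_w_r log odds ratio from the logistic regression of the
#'   observation indicator on the collider (conventionally adjusted for the
#'   exposure; see `w_adjusted`).
#' @param probit_factor logit-to-probit conversion constant (default 0.6).
#' @param w_adjusted logical flag recording whether `logor_w_r` came from a
#'   model adjusted for the exposure rather than a marginal model; carried
#'   into reports because the covariance form is written for a marginal
#'   covariance while applied practice substitutes the adjusted estimate.
#' @return object of class `summary_stats`.
#' @export
summary_stats <- function(var_x, var_w, cov_yw, logor_x_r, logor_w_r,
                          probit_factor = 0.6, w_adjusted = TRUE) {
  if (var_x <= 0 || var_w <= 0) stop("variances must be strictly positive")
  structure(list(var_x = var_x, var_w = var_w, cov_yw = cov_yw,
                 logor_x_r = logor_x_r, logor_w_r = logor_w_r,
                 probit_factor = probit_factor, w_adjusted = w_adjusted),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, digits = 4, ...) {
  cat("Summary statistics for plug-in maximum bias\n")
  cat(sprintf("  Var(X) = %.*g, Var(W) = %.*g, Cov(Y,W) = %.*g\n",
              digits, x$var_x, digits, x$var_w, digits, x$cov_yw))
  cat(sprintf("  logOR(X -> observed) = %.*g, logOR(W -> observed) = %.*g%s\n",
              digits, x$logor_x_r, digits, x$logor_w_r,
              if (isTRUE(x$w_adjusted)) " (adjusted for X)" else ""))
  cat(sprintf("  probit conversion factor = %g\n", x$probit_factor))
  invisible(x)
}

#' Summary statistics implied by an outcome-missing path model
#'
#' Computes the [summary_stats()] inputs directly from a path model's
#' implied moments, standardizing the latent missingness variable to unit
#' variance. Used to verify that the covariance form agrees with the
#' direct-effects formula.
#'
#' @inheritParams max_bias_outcome
#' @return a [summary_stats()].
#' @export
summary_stats_from_model <- function(model) {
  joint <- implied_moments(model)
  X <- role_var(model, "exposure"); W <- role_var(model, "collider")
  Y <- role_var(model, "outcome"); R <- role_var(model, "missingness")
  sd_r <- sqrt(joint$sigma[R, R])
  var_x <- joint$sigma[X, X]; var_w <- joint$sigma[W, W]
  cov_xr <- joint$sigma[X, R] / sd_r
  cov_wr <- joint$sigma[W, R] / sd_r
  summary_stats(
    var_x = var_x, var_w = var_w, cov_yw = joint$sigma[Y, W],
    logor_x_r = cov_xr / (0.6 * var_x),
    logor_w_r = cov_wr / (0.6 * var_w),
    probit_factor = 0.6, w_adjusted = FALSE
  )
}

#' Covariance-form maximum bias (plug-in formula)
#'
#' The applied version of the maximum-bias formula, expressed in the
#' variances and covariances of the observed (or partially observed)
#' variables with the latent missingness variable `R` standardized to unit
#' variance:
#'
#' \deqn{\frac{\mathrm{Cov}(X,R)\,\mathrm{Cov}(W,R)\,\mathrm{Cov}(Y,W)}
#'   {\{\mathrm{Var}(X)-\mathrm{Cov}^2(X,R)\}\mathrm{Var}(W)
#'    - \mathrm{Var}(X)\,\mathrm{Cov}^2(W,R)}}
#'
#' with `Cov(., R) = factor * logOR * Var(.)` recovered from the logistic
#' regressions of the observation indicator (probit conversion, 0.6 rule).
#'
#' @param stats a [summary_stats()].
#' @return signed maximum bias (numeric scalar).
#' @export
#' @examples
#' s <- summary_stats(var_x = 0.228, var_w = 0.286, cov_yw = 0.171,
#'                    logor_x_r = log(2.31), logor_w_r = log(1.15))
#' max_bias_covform(s)  # ~0.008
max_bias_covform <- function(stats) {
  stopifnot(inherits(stats, "summary_stats"))
  f <- stats$probit_factor
  cov_xr <- f * stats$logor_x_r * stats$var_x
  cov_wr <- f * stats$logor_w_r * stats$var_w
  den <- (stats$var_x - cov_xr^2) * stats$var_w - stats$var_x * cov_wr^2
  if (den <= 0) {
    stop("non-positive denominator: the covariance form is outside its ",
         "valid regime (implied Cov(X,R) or Cov(W,R) too large)")
  }
  cov_xr * cov_wr * stats$cov_yw / den
}

#' Maximum bias of the imputation-model exposure coefficient when the
#' exposure is partially observed
#'
#' For the exposure-missing structure (`"fig4"`), the imputation model for
#' `X` regresses it on `Y` and the collider `W`; its coefficient on `Y`
#' (`alpha_1`), estimated on complete records, has maximum bias
#'
#' \deqn{\frac{A\{\mathrm{Var}(Y)\mathrm{Cov}(Y,X|W)
#'   - \mathrm{Cov}(Y,X)\mathrm{Var}(Y|W)\}}
#'   {\mathrm{Var}(Y|W)\{\mathrm{Var}(Y|W) - A\,\mathrm{Var}(Y)\}},
#'   \quad A = \frac{\mathrm{Cov}^2(R,W)}{\mathrm{Var}(R)\mathrm{Var}(W)}}
#'
#' with all moments taken from the implied joint distribution.
#'
#' @param model a [path_model()] with the exposure-missing (`"fig4"`) role
#'   structure.
#' @return signed maximum bias of `alpha_1` (numeric scalar).
#' @export
#' @examples
#' max_bias_exposure_alpha1(path_model_preset("fig4"))  # -1/104
max_bias_exposure_alpha1 <- function(model) {
  stopifnot(inherits(model, "path_model"))
  Y <- role_var(model, "outcome"); X <- role_var(model, "exposure")
  W <- role_var(model, "collider"); R <- role_var(model, "missingness")
  if (path_coef(model, R, X) != 0) {
    stop("model does not have the exposure-missing (fig4/fig6) structure")
  }
  joint <- implied_moments(model)
  A <- joint$sigma[R, W]^2 / (joint$sigma[R, R] * joint$sigma[W, W])
  var_y <- joint$sigma[Y, Y]
  cov_yx <- joint$sigma[Y, X]
  cov_yx_w <- cond_cov(joint, Y, X, W)
  var_y_w <- cond_cov(joint, Y, Y, W)
  den <- var_y_w * (var_y_w - A * var_y)
  if (abs(den) < .Machine$double.eps * var_y^2) {
    stop("degenerate denominator in the exposure-case maximum-bias formula")
  }
  A * (var_y * cov_yx_w - cov_yx * var_y_w) / den
}

#' Standard-error profile of the MI and complete-records estimators
#'
#' Endpoint standard errors of the MI estimator (imputation model with the
#' exposure and the collider) and of the complete-records (CRA) estimator
#' for the outcome-missing structure, at missingness proportion 0 and in
#' the limit as it tends to 1, for `n_observed` observed outcome values:
#'
#' * `se_mi_at_0`: `sqrt((Var(Y) - b^2 Var(X) - Cov^2(Y,W)/Var(W)) / (n Var(X)))`
#' * `se_mi_limit`: `sqrt(Var(Y|X,W,R) / (n Var(X|W,R)))`
#' * `se_cra_at_0`: `sqrt((Var(Y) - b^2 Var(X)) / (n Var(X)))`
#' * `se_cra_limit`: `sqrt((Var(Y) - b^2 Var(X)) / (n (Var(X) - Cov^2(X,R)/Var(R))))`
#'
#' where `b` is the marginal population slope of `Y` on `X`. The MI limit
#' is evaluated through conditional moments (residual variance of `Y` given
#' `X`, `W`, `R`), which is algebraically identical to the expanded
#' quadratic form and numerically stabler.
#'
#' @inheritParams max_bias_outcome
#' @param n_observed number of records with an observed outcome (>= 2).
#' @return object of class `bias_report` with fields `max_bias`,
#'   `bias_lower`, `direction`, `se_mi_at_0`, `se_mi_limit`, `se_cra_at_0`,
#'   `se_cra_limit`, `relative_precision_pct` (at the missingness limit)
#'   and `n_observed`.
#' @export
#' @examples
#' se_profile(path_model_preset("fig1"), n_observed = 1000)
se_profile <- function(model, n_observed) {
  stopifnot(inherits(model, "path_model"))
  if (!is.numeric(n_observed) || n_observed < 2) {
    stop("`n_observed` must be at least 2")
  }
  Y <- role_var(model, "outcome"); X <- role_var(model, "exposure")
  W <- role_var(model, "collider"); R <- role_var(model, "missingness")
  joint <- implied_moments(model)
  n <- n_observed
  var_y <- joint$sigma[Y, Y]; var_x <- joint$sigma[X, X]
  var_w <- joint$sigma[W, W]; var_r <- joint$sigma[R, R]
  b_yx <- joint$sigma[Y, X] / var_x
  num_mi0 <- var_y - b_yx^2 * var_x - joint$sigma[Y, W]^2 / var_w
  num_cra <- var_y - b_yx^2 * var_x
  se_mi_at_0 <- sqrt(num_mi0 / (n * var_x))
  se_cra_at_0 <- sqrt(num_cra / (n * var_x))
  se_mi_limit <- sqrt(cond_cov(joint, Y, Y, c(X, W, R)) /
                        (n * cond_cov(joint, X, X, c(W, R))))
  se_cra_limit <- sqrt(num_cra /
                         (n * (var_x - joint$sigma[X, R]^2 / var_r)))
  mb <- max_bias_outcome(model)
  structure(
    list(max_bias = mb, bias_lower = 0, direction = sign(mb),
         se_mi_at_0 = unname(se_mi_at_0), se_mi_limit = unname(se_mi_limit),
         se_cra_at_0 = unname(se_cra_at_0),
         se_cra_limit = unname(se_cra_limit),
         relative_precision_pct = relative_precision(se_mi_limit,
                                                     se_cra_limit),
         n_observed = n_observed),
    class = "bias_report")
}

#' @export
print.bias_report <- function(x, digits = 4, ...) {
  cat("Collider-auxiliary bias/SE report (n observed =", x$n_observed, ")\n")
  cat(sprintf("  bias in [0, %.*g] (sign %+d)\n", digits, abs(x$max_bias),
              as.integer(x$direction)))
  cat(sprintf("  SE(MI)  : %.*g at pi0=0  ->  %.*g as pi0->1\n",
              digits, x$se_mi_at_0, digits, x$se_mi_limit))
  cat(sprintf("  SE(CRA) : %.*g at pi0=0  ->  %.*g as pi0->1\n",
              digits, x$se_cra_at_0, digits, x$se_cra_limit))
  cat(sprintf("  relative precision of MI vs CRA at the limit: %.1f%%\n",
              x$relative_precision_pct))
  invisible(x)
}

#' Relative increase in precision of the MI over the CRA estimator
#'
#' `100 * (1 - se_mi^2 / se_cra^2)`: positive when MI is more precise.
#'
#' @param se_mi,se_cra positive standard errors.
#' @return percentage (numeric scalar).
#' @export
relative_precision <- function(se_mi, se_cra) {
  if (se_mi <= 0 || se_cra <= 0) stop("standard errors must be positive")
  100 * (1 - se_mi^2 / se_cra^2)
}

#' Logit to probit conversion (0.6 rule)
#'
#' A logistic-regression coefficient (log odds ratio) corresponds
#' approximately to a probit coefficient of `0.6 * logOR`; the conversion
#' is valid unless the proportion of complete records is very close to 0
#' or 1. `logor_from_probit()` is the inverse map, so the implied odds
#' ratio of a probit coefficient `b` is `exp(b / 0.6)`.
#'
#' @param log_odds_ratio,probit_coef coefficient to convert.
#' @param factor conversion constant (default 0.6).
#' @return converted coefficient (numeric scalar).
#' @export
#' @examples
#' exp(logor_from_probit(0.5))   # odds ratio ~2.30
#' probit_from_logor(log(2.31))  # ~0.50
probit_from_logor <- function(log_odds_ratio, factor = 0.6) {
  factor * log_odds_ratio
}

#' @rdname probit_from_logor
#' @export
logor_from_probit <- function(probit_coef, factor = 0.6) {
  probit_coef / factor
}
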
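#' Ordinary least squares on the complete rows of a dataset
#'
#' Fits `response ~ predictors` by OLS on the rows that are complete for
#' the fitted variables, returning the coefficients, the residual variance
#' with denominator `n - p - 1`, and the coefficient covariance matrix.
#'
#' @param data a data frame.
#' @param response name of the response.
#' @param predictors character vector of predictor names (may be empty).
#' @return object of class `ols_fit`: list with `coefficients` (including
#'   `(Intercept)`), `residual_variance`, `vcov`, `n`, `df`.
#' @export
ols_fit <- function(data, response, predictors = character(0)) {
  vars <- c(response, predictors)
  if (length(bad <- setdiff(vars, names(data)))) {
    stop("unknown variable(s): ", paste(bad, collapse = ", "))
  }
  keep <- stats::complete.cases(data[vars])
  y <- data[[response]][keep]
  Xm <- cbind("(Intercept)" = 1,
              as.matrix(as.data.frame(data[keep, predictors, drop = FALSE])))
  p <- ncol(Xm) - 1
  if (length(y) < p + 2) {
    stop("insufficient complete rows (", length(y), ") for ", p + 1,
         " parameters")
  }
  qx <- qr(Xm)
  if (qx$rank < ncol(Xm)) stop("singular design matrix")
  coefs <- qr.coef(qx, y)
  res <- y - drop(Xm %*% coefs)
  df <- length(y) - p - 1
  s2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(Xm), colnames(Xm))
  structure(list(coefficients = coefs, residual_variance = s2,
                 vcov = s2 * xtx_inv, n = length(y), df = df),
            class = "ols_fit")
}

#' Proper normal-linear multiple imputation
#'
#' Imputes the missing entries of `target` from a Bayesian normal linear
#' regression on fully observed predictors, under the standard
#' noninformative prior: for each imputation the residual variance is
#' drawn from its scaled inverse-chi-squared posterior, the coefficients
#' from their Gaussian posterior given that variance, and the missing
#' entries as linear predictor plus Gaussian noise. This is proper
#' imputation, so Rubin's-rules variances are calibrated.
#'
#' @param data a data frame in which `target` has missing entries and the
#'   predictors are fully observed.
#' @param target name of the partially observed variable.
#' @param predictors imputation-model predictors.
#' @param m number of imputations (>= 2).
#' @param seed integer seed.
#' @return list of `m` completed data frames.
#' @export
#' @examples
#' m <- path_model_preset("fig1")
#' d <- simulate_complete(m, 500, seed = 1)
#' d <- impose_missingness(d, missingness_spec("Y", pi0 = 0.5))
#' imp <- impute_normal(d, "Y", c("X", "W"), m = 5, seed = 2)
impute_normal <- function(data, target, predictors, m = 100, seed = 1) {
  if (m < 2) stop("`m` must be at least 2")
  if (length(bad <- setdiff(c(target, predictors), names(data)))) {
    stop("unknown variable(s): ", paste(bad, collapse = ", "))
  }
  miss <- is.na(data[[target]])
  if (!any(miss)) {
    stop("`", target, "` has no missing entries; nothing to impute")
  }
  pred_df <- as.data.frame(data[predictors])
  if (anyNA(pred_df)) {
    stop("imputation predictors must be fully observed")
  }
  y_obs <- data[[target]][!miss]
  X_obs <- cbind(1, as.matrix(pred_df[!miss, , drop = FALSE]))
  X_mis <- cbind(1, as.matrix(pred_df[miss, , drop = FALSE]))
  qx <- qr(X_obs)
  if (qx$rank < ncol(X_obs)) stop("singular imputation design matrix")
  bhat <- qr.coef(qx, y_obs)
  res <- y_obs - drop(X_obs %*% bhat)
  df <- length(y_obs) - ncol(X_obs)
  if (df < 1) stop("insufficient observed rows to fit the imputation model")
  rss <- sum(res^2)
  Rinv <- backsolve(qr.R(qx), diag(ncol(X_obs)))
  set.seed(seed)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    sigma2 <- rss / stats::rchisq(1, df)
    beta <- bhat + drop(Rinv %*% stats::rnorm(ncol(X_obs))) * sqrt(sigma2)
    completed <- data
    completed[[target]][miss] <- drop(X_mis %*% beta) +
      stats::rnorm(sum(miss), 0, sqrt(sigma2))
    out[[j]] <- completed
  }
  out
}

#' Bayesian logistic imputation for a binary target (experimental)
#'
#' Imputes missing entries of a binary variable from a logistic
#' regression: for each imputation the coefficients are drawn from the
#' Gaussian approximation to their posterior (maximum likelihood estimate
#' and inverse information), and missing entries are sampled as Bernoulli
#' with the drawn linear predictor. Provided for the binary-variable
#' extension, where results from the continuous case transfer only
#' approximately via the underlying-normal argument; treat as
#' experimental.
#'
#' @inheritParams impute_normal
#' @return list of `m` completed data frames.
#' @export
impute_binary <- function(data, target, predictors, m = 100, seed = 1) {
  if (m < 2) stop("`m` must be at least 2")
  miss <- is.na(data[[target]])
  if (!any(miss)) {
    stop("`", target, "` has no missing entries; nothing to impute")
  }
  obsvals <- stats::na.omit(data[[target]])
  if (length(unique(obsvals)) > 2) stop("`", target, "` is not binary")
  pred_df <- as.data.frame(data[predictors])
  if (anyNA(pred_df)) stop("imputation predictors must be fully observed")
  fml <- stats::as.formula(paste(target, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, data = data,
                                     family = stats::binomial()))
  bhat <- stats::coef(fit)
  ch <- chol(stats::vcov(fit))
  X_mis <- cbind(1, as.matrix(pred_df[miss, , drop = FALSE]))
  set.seed(seed)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    beta <- bhat + drop(t(ch) %*% stats::rnorm(length(bhat)))
    p <- stats::plogis(drop(X_mis %*% beta))
    completed <- data
    completed[[target]][miss] <- stats::rbinom(sum(miss), 1, p)
    out[[j]] <- completed
  }
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' `Qbar = mean(estimates)`, within-imputation variance `W =
#' mean(variances)`, between-imputation variance `B = var(estimates)`,
#' total variance `T = W + (1 + 1/m) B`, standard error `sqrt(T)`, and the
#' classical degrees of freedom `(m - 1) (1 + W / ((1 + 1/m) B))^2`
#' (infinite when `B = 0`).
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation squared standard errors.
#' @return object of class `mi_result`: list with `pooled_estimate`,
#'   `within_var`, `between_var`, `total_var`, `se`, `dof`, `m`,
#'   `per_imputation_estimates`.
#' @export
#' @examples
#' pool_rubin(c(1, 3), c(1, 1))  # estimate 2, total variance 4
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) stop("need at least 2 imputations to pool")
  if (length(variances) != m) {
    stop("`estimates` and `variances` must have equal length")
  }
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  tv <- w + (1 + 1 / m) * b
  dof <- if (b > 0) (m - 1) * (1 + w / ((1 + 1 / m) * b))^2 else Inf
  structure(list(pooled_estimate = qbar, within_var = w, between_var = b,
                 total_var = tv, se = sqrt(tv), dof = dof, m = m,
                 per_imputation_estimates = estimates),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, digits = 4, ...) {
  cat(sprintf("MI pooled estimate %.*g (SE %.*g), m = %d\n",
              digits, x$pooled_estimate, digits, x$se, x$m))
  cat(sprintf("  within %.*g, between %.*g, total %.*g, dof %.3g\n",
              digits, x$within_var, digits, x$between_var, digits,
              x$total_var, x$dof))
  invisible(x)
}

#' Multiple imputation analysis: impute, fit, pool
#'
#' Runs [impute_normal()] on the imputation model, fits the analysis model
#' by [ols_fit()] to each completed dataset, and pools the coefficient of
#' interest with [pool_rubin()]. Also records `alpha1_obs`, the
#' complete-records coefficient on the first imputation-model predictor
#' (the quantity the MI estimator converges to as the number of
#' imputations grows, in the outcome-missing setting).
#'
#' @param data a data frame.
#' @param response,predictors the analysis model.
#' @param imp_target,imp_predictors the imputation model.
#' @param m number of imputations.
#' @param seed integer seed.
#' @param parameter name of the analysis coefficient to pool (default: the
#'   first analysis predictor).
#' @return an `mi_result` with extra fields `parameter`, `alpha1_obs` and
#'   `ci` (95% interval using the t distribution with Rubin degrees of
#'   freedom).
#' @export
mi_analyze <- function(data, response, predictors, imp_target,
                       imp_predictors, m = 100, seed = 1,
                       parameter = predictors[1]) {
  completed <- impute_normal(data, imp_target, imp_predictors, m = m,
                             seed = seed)
  ests <- numeric(m); vars <- numeric(m)
  for (j in seq_len(m)) {
    fit <- ols_fit(completed[[j]], response, predictors)
    ests[j] <- fit$coefficients[[parameter]]
    vars[j] <- fit$vcov[parameter, parameter]
  }
  pooled <- pool_rubin(ests, vars)
  imp_fit <- ols_fit(data, imp_target, imp_predictors)
  pooled$parameter <- parameter
  pooled$alpha1_obs <- unname(imp_fit$coefficients[[imp_predictors[1]]])
  half <- stats::qt(0.975, pooled$dof) * pooled$se
  pooled$ci <- c(pooled$pooled_estimate - half, pooled$pooled_estimate + half)
  pooled
}

#' Complete-records (complete-case) estimate
#'
#' OLS restricted to records complete for the analysis-model variables.
#'
#' @inheritParams mi_analyze
#' @return list with `estimate`, `se`, `ci` (95%, t distribution), `n`.
#' @export
cra_estimate <- function(data, response, predictors,
                         parameter = predictors[1]) {
  fit <- ols_fit(data, response, predictors)
  est <- fit$coefficients[[parameter]]
  se <- sqrt(fit$vcov[parameter, parameter])
  half <- stats::qt(0.975, fit$df) * se
  list(estimate = unname(est), se = unname(se),
       ci = c(est - half, est + half), n = fit$n)
}
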
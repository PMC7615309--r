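# One Monte-Carlo replicate: simulate, mask by the latent-R order
# statistic (fixed number of observed records), impute m times with proper
# posterior draws, fit the analysis slope per imputation, pool.
#
# Vectorized across imputations so that sweeps over hundreds of replicates
# stay fast; agreement with the reference route
# (impute_normal + ols_fit + pool_rubin) is checked in the test suite.
#
# Returns c(mi, mi_var, mi_dof, cra, cra_var, alpha1_obs, n_total).
.mi_rep <- function(model, pi0, n_obs, m, imp_target, imp_predictors,
                    response, exposure, seed) {
  R <- role_var(model, "missingness")
  n_total <- if (pi0 > 0) as.integer(round(n_obs / (1 - pi0))) else
    as.integer(n_obs)
  dat <- .simulate_matrix(model, n_total, seed)
  x_all <- dat[, exposure]
  y_all <- dat[, response]

  if (pi0 <= 0) {
    sl <- .slope_fit(x_all, y_all)
    alpha1 <- qr.coef(qr(cbind(1, dat[, imp_predictors, drop = FALSE])),
                      dat[, imp_target])[2]
    return(c(mi = sl[["slope"]], mi_var = sl[["var"]], mi_dof = n_total - 2,
             cra = sl[["slope"]], cra_var = sl[["var"]],
             alpha1_obs = unname(alpha1), n_total = n_total))
  }

  obs <- order(dat[, R])[seq_len(n_obs)]
  mis <- setdiff(seq_len(n_total), obs)
  n_mis <- length(mis)

  # imputation model on the observed records
  Zo <- cbind(1, dat[obs, imp_predictors, drop = FALSE])
  zq <- qr(Zo)
  bhat <- qr.coef(zq, dat[obs, imp_target])
  rss <- sum(qr.resid(zq, dat[obs, imp_target])^2)
  df <- n_obs - ncol(Zo)
  Rinv <- backsolve(qr.R(zq), diag(ncol(Zo)))
  Zm <- cbind(1, dat[mis, imp_predictors, drop = FALSE])

  set.seed(.var_seed(seed, ".mi_draws"))
  sigma2 <- rss / stats::rchisq(m, df)
  betas <- bhat + Rinv %*% matrix(stats::rnorm(ncol(Zo) * m), ncol = m) *
    rep(sqrt(sigma2), each = ncol(Zo))
  Imp <- Zm %*% betas +
    matrix(stats::rnorm(n_mis * m), ncol = m) * rep(sqrt(sigma2), each = n_mis)

  # analysis slope of response on exposure; one of the two is imputed
  if (imp_target == response) {
    fix <- x_all; fix_m <- x_all[mis]
    s_f <- sum(fix); s_ff <- sum(fix^2)
    s_v <- sum(y_all[obs]) + colSums(Imp)
    s_vv <- sum(y_all[obs]^2) + colSums(Imp^2)
    s_fv <- sum(x_all[obs] * y_all[obs]) + colSums(fix_m * Imp)
    sxx <- s_ff - s_f^2 / n_total
    sxy <- s_fv - s_f * s_v / n_total
    syy <- s_vv - s_v^2 / n_total
    slopes <- sxy / sxx
    uvar <- (syy - slopes * sxy) / ((n_total - 2) * sxx)
  } else if (imp_target == exposure) {
    fix <- y_all
    s_y <- sum(fix); s_yy <- sum(fix^2)
    s_x <- sum(x_all[obs]) + colSums(Imp)
    s_xx <- sum(x_all[obs]^2) + colSums(Imp^2)
    s_xy <- sum(x_all[obs] * fix[obs]) + colSums(fix[mis] * Imp)
    sxx <- s_xx - s_x^2 / n_total
    sxy <- s_xy - s_x * s_y / n_total
    syy <- s_yy - s_y^2 / n_total
    slopes <- sxy / sxx
    uvar <- (syy - slopes * sxy) / ((n_total - 2) * sxx)
  } else {
    stop("the imputation target must be the analysis response or exposure")
  }

  qbar <- mean(slopes)
  w <- mean(uvar)
  b <- stats::var(slopes)
  tot <- w + (1 + 1 / m) * b
  dof <- if (b > 0) (m - 1) * (1 + w / ((1 + 1 / m) * b))^2 else Inf

  cra <- .slope_fit(x_all[obs], y_all[obs])
  c(mi = qbar, mi_var = tot, mi_dof = dof,
    cra = cra[["slope"]], cra_var = cra[["var"]],
    alpha1_obs = unname(bhat[2]), n_total = n_total)
}

# Light replicate for the large-m identification of the MI estimator:
# alpha1_obs, the imputation-model coefficient on the complete records,
# and the CRA slope, each with its model-based variance. No imputation is
# performed, so this is cheap enough for fine crossover grids.
.a1_rep <- function(model, pi0, n_obs, imp_predictors, response, exposure,
                    seed) {
  R <- role_var(model, "missingness")
  n_total <- if (pi0 > 0) as.integer(round(n_obs / (1 - pi0))) else
    as.integer(n_obs)
  dat <- .simulate_matrix(model, n_total, seed)
  obs <- if (pi0 > 0) order(dat[, R])[seq_len(n_obs)] else seq_len(n_total)
  Zo <- cbind(1, dat[obs, imp_predictors, drop = FALSE])
  zq <- qr(Zo)
  y <- dat[obs, response]
  a1 <- qr.coef(zq, y)[2]
  s2 <- sum(qr.resid(zq, y)^2) / (n_obs - ncol(Zo))
  v_a1 <- (s2 * chol2inv(qr.R(zq)))[2, 2]
  cra <- .slope_fit(dat[obs, exposure], y)
  c(a1 = unname(a1), a1_var = v_a1,
    cra = cra[["slope"]], cra_var = cra[["var"]])
}

.slope_fit <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  syy <- sum(y^2) - sum(y)^2 / n
  slope <- sxy / sxx
  c(slope = slope, var = (syy - slope * sxy) / ((n - 2) * sxx))
}

.rep_seed <- function(seed, rep) {
  as.integer((as.numeric(seed) * 69621 + rep * 7907) %% 2147483647)
}

# Shared replicate loop returning a reps x 7 matrix.
.run_reps <- function(model, pi0, n_obs, reps, m, imp_target,
                      imp_predictors, response, exposure, seed) {
  out <- matrix(NA_real_, reps, 7)
  for (r in seq_len(reps)) {
    out[r, ] <- .mi_rep(model, pi0, n_obs, m, imp_target, imp_predictors,
                        response, exposure, .rep_seed(seed, r))
  }
  colnames(out) <- c("mi", "mi_var", "mi_dof", "cra", "cra_var",
                     "alpha1_obs", "n_total")
  out
}

# Default masked variable / imputation predictors / analysis pair for a
# scenario, by roles: if the missingness variable has the outcome's
# structure (fig1 family) the outcome is masked and imputed from
# {exposure, collider}; otherwise the exposure is masked and imputed from
# {outcome, collider}.
.default_design <- function(model) {
  Y <- role_var(model, "outcome"); X <- role_var(model, "exposure")
  W <- role_var(model, "collider")
  outcome_missing <- path_coef(model, role_var(model, "missingness"), X) != 0 ||
    path_coef(model, X, role_var(model, "predictor")) == 0
  if (outcome_missing) {
    list(imp_target = Y, imp_predictors = c(X, W), response = Y,
         exposure = X)
  } else {
    list(imp_target = X, imp_predictors = c(Y, W), response = Y,
         exposure = X)
  }
}

#' Monte-Carlo sweep over the missingness proportion
#'
#' Reproduces the bias/SE-versus-missingness design: for each missingness
#' proportion `pi0` in the grid, replicate datasets are generated with the
#' number of observed records held fixed at `n_obs` (total rows inflated
#' to `n_obs / (1 - pi0)`), the masked variable is imputed `m` times with
#' the collider in the imputation model, and the pooled analysis slope and
#' the complete-records slope are recorded. Empirical columns are averaged
#' over replicates; analytic reference columns (the maximum-bias bound and
#' the endpoint standard errors) are replicate-independent.
#'
#' @param model a [path_model()] with the outcome-missing structure.
#' @param pi0_grid missingness proportions in `[0, 1)`.
#' @param n_obs number of observed records per dataset.
#' @param reps replicates per grid point (>= 2).
#' @param m imputations per replicate.
#' @param seed integer seed.
#' @param imp_predictors imputation-model predictors (default exposure and
#'   collider).
#' @return a `sweep_result` data frame with one row per grid point:
#'   `pi0`, `mean_bias`, `emp_se_mi`, `emp_se_cra`, `mean_alpha1_obs`,
#'   analytic columns `max_bias`, `se_mi_at_0`, `se_mi_limit`,
#'   `se_cra_at_0`, `se_cra_limit`, and bookkeeping `reps`, `n_obs`, `m`,
#'   `seed`.
#' @export
sweep_pi0 <- function(model, pi0_grid, n_obs = 1000, reps = 500, m = 20,
                      seed = 1, imp_predictors = NULL) {
  if (any(pi0_grid < 0 | pi0_grid >= 1)) {
    stop("`pi0_grid` must lie in [0, 1)")
  }
  if (reps < 2) stop("`reps` must be at least 2")
  des <- .default_design(model)
  if (!is.null(imp_predictors)) des$imp_predictors <- imp_predictors
  joint <- implied_moments(model)
  true_slope <- joint$sigma[des$response, des$exposure] /
    joint$sigma[des$exposure, des$exposure]
  prof <- se_profile(model, n_obs)
  rows <- lapply(pi0_grid, function(p) {
    rr <- .run_reps(model, p, n_obs, reps, m, des$imp_target,
                    des$imp_predictors, des$response, des$exposure,
                    .rep_seed(seed, round(1e4 * p)))
    data.frame(pi0 = p,
               mean_bias = mean(rr[, "mi"]) - true_slope,
               emp_se_mi = stats::sd(rr[, "mi"]),
               emp_se_cra = stats::sd(rr[, "cra"]),
               mean_alpha1_obs = mean(rr[, "alpha1_obs"]),
               emp_se_alpha1 = stats::sd(rr[, "alpha1_obs"]),
               max_bias = prof$max_bias,
               se_mi_at_0 = prof$se_mi_at_0, se_mi_limit = prof$se_mi_limit,
               se_cra_at_0 = prof$se_cra_at_0,
               se_cra_limit = prof$se_cra_limit,
               reps = reps, n_obs = n_obs, m = m, seed = seed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Sweep the direct effect sizes
#'
#' Evaluates the analytic maximum bias over a grid of path-coefficient
#' values (the outcome-missing formula for `"fig1"`, the
#' imputation-coefficient formula for `"fig4"`), optionally adding
#' simulated MI bias at a fixed missingness proportion (`"fig6"` has no
#' closed form here and is simulation-only). One row per grid cell; the
#' cells over nuisance coefficients (e.g. the unmeasured-cause paths) are
#' retained so they can be marginalized into box plots.
#'
#' @param scenario `"fig1"`, `"fig4"` or `"fig6"`.
#' @param varying named list of coefficient grids, names `"child~parent"`,
#'   e.g. `list("Y~Z" = c(0, 0.5, 1), "W~Z" = c(0, 0.5, 1))`.
#' @param fixed_pi0 missingness proportion used for the simulated columns.
#' @param reps simulated replicates per cell; `0` for analytic-only.
#' @param n_obs,m,seed simulation settings as in [sweep_pi0()].
#' @return a `sweep_result` data frame: one column per varied coefficient,
#'   `analytic_max_bias` (NA where no closed form applies), and when
#'   `reps > 0` the columns `sim_bias`, `sim_se` plus bookkeeping.
#' @export
sweep_effects <- function(scenario = c("fig1", "fig4", "fig6"), varying,
                          fixed_pi0 = 0.5, reps = 0, n_obs = 1000, m = 20,
                          seed = 1) {
  scenario <- match.arg(scenario)
  if (!length(varying) || is.null(names(varying))) {
    stop("`varying` must be a named list of coefficient grids")
  }
  grid <- expand.grid(varying, KEEP.OUT.ATTRS = FALSE)
  out <- grid
  out$analytic_max_bias <- NA_real_
  if (reps > 0) { out$sim_bias <- NA_real_; out$sim_se <- NA_real_ }
  for (i in seq_len(nrow(grid))) {
    coefs <- stats::setNames(as.numeric(grid[i, , drop = TRUE]),
                             names(varying))
    mod <- path_model_preset(scenario, coefficients = coefs)
    out$analytic_max_bias[i] <- switch(scenario,
      fig1 = max_bias_outcome(mod),
      fig4 = max_bias_exposure_alpha1(mod),
      fig6 = NA_real_)
    if (reps > 0) {
      Ynm <- role_var(mod, "outcome"); Xnm <- role_var(mod, "exposure")
      Wnm <- role_var(mod, "collider")
      des <- if (scenario == "fig1") {
        list(imp_target = Ynm, imp_predictors = c(Xnm, Wnm),
             response = Ynm, exposure = Xnm)
      } else {
        list(imp_target = Xnm, imp_predictors = c(Ynm, Wnm),
             response = Ynm, exposure = Xnm)
      }
      joint <- implied_moments(mod)
      true_slope <- joint$sigma[des$response, des$exposure] /
        joint$sigma[des$exposure, des$exposure]
      rr <- .run_reps(mod, fixed_pi0, n_obs, reps, m, des$imp_target,
                      des$imp_predictors, des$response, des$exposure,
                      .rep_seed(seed, i))
      out$sim_bias[i] <- mean(rr[, "mi"]) - true_slope
      out$sim_se[i] <- stats::sd(rr[, "mi"])
    }
  }
  out$scenario <- scenario
  out$pi0 <- fixed_pi0
  out$reps <- reps; out$n_obs <- n_obs; out$m <- m; out$seed <- seed
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Locate the missingness proportion at which the MI and CRA standard
#' errors cross
#'
#' Estimates, by simulation, the proportion of missing data `pi0*` at
#' which the standard error of the MI estimator (collider in the
#' imputation model) first exceeds that of the complete-records
#' estimator. Both standard errors are computed from the same replicate
#' datasets at each grid point (common random numbers), the difference is
#' smoothed by a quadratic fit across the grid, and the root of the
#' smooth is returned.
#'
#' With `estimator = "alpha1"` (default) the MI estimator is represented
#' by its many-imputations limit, the imputation-model coefficient on the
#' complete records: this is the quantity whose standard error runs from
#' the collider-adjusted value at no missingness to the
#' `R`-conditional value as the missingness proportion tends to 1, and it
#' requires no imputation draws. With `estimator = "pooled"` the literal
#' finite-`m` pooled analysis slope is used; its standard error carries
#' the additional Monte-Carlo and collider-projection noise of order
#' `1/m` and `1/sqrt(n)`, which moves the crossing to smaller `pi0`.
#'
#' With `se_method = "model"` (default) each arm's standard error at a
#' grid point is the average of the model-based per-replicate standard
#' errors (low Monte-Carlo noise); `"empirical"` uses the standard
#' deviation of the estimates across replicates.
#'
#' @param model a [path_model()] with the outcome-missing structure.
#' @param n_obs observed records per dataset.
#' @param reps replicates per grid point.
#' @param m imputations per replicate (used by `estimator = "pooled"`).
#' @param seed integer seed.
#' @param grid missingness proportions scanned.
#' @param estimator `"alpha1"` or `"pooled"` (see Details).
#' @param se_method `"model"` or `"empirical"` (see Details).
#' @param tol root-finding tolerance on `pi0`.
#' @return `pi0*` (numeric scalar in `(0, 1)`); errors if the smoothed
#'   difference has no sign change on the grid.
#' @export
#' @examples
#' \donttest{
#' mod <- path_model_preset("fig1", coefficients = c("Y~Z" = 0.5, "W~Z" = 0.5))
#' find_se_crossover(mod, reps = 500, seed = 1)  # ~0.4
#' }
find_se_crossover <- function(model, n_obs = 1000, reps = 500, m = 20,
                              seed = 1, grid = seq(0.1, 0.7, by = 0.1),
                              estimator = c("alpha1", "pooled"),
                              se_method = c("model", "empirical"),
                              tol = 1e-3) {
  estimator <- match.arg(estimator)
  se_method <- match.arg(se_method)
  des <- .default_design(model)
  d <- vapply(seq_along(grid), function(i) {
    if (estimator == "alpha1") {
      rr <- t(vapply(seq_len(reps), function(r) {
        .a1_rep(model, grid[i], n_obs, des$imp_predictors, des$response,
                des$exposure, .rep_seed(.rep_seed(seed, i), r))
      }, numeric(4)))
      mi_col <- "a1"; mi_var <- "a1_var"
    } else {
      rr <- .run_reps(model, grid[i], n_obs, reps, m, des$imp_target,
                      des$imp_predictors, des$response, des$exposure,
                      .rep_seed(seed, i))
      mi_col <- "mi"; mi_var <- "mi_var"
    }
    if (se_method == "model") {
      mean(sqrt(rr[, mi_var])) - mean(sqrt(rr[, "cra_var"]))
    } else {
      stats::sd(rr[, mi_col]) - stats::sd(rr[, "cra"])
    }
  }, 0)
  fit <- stats::lm(d ~ poly(grid, 2, raw = TRUE))
  f <- function(p) drop(cbind(1, p, p^2) %*% stats::coef(fit))
  lo <- min(grid); hi <- max(grid)
  if (f(lo) * f(hi) > 0) {
    stop("no SE crossing of the smoothed difference on [",
         lo, ", ", hi, "]")
  }
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}
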
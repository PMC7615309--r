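test_that("OLS recovers exact linear data and population slopes", {
  d <- data.frame(x = 1:20, w = rep(c(0, 1), 10))
  d$y <- 2 + 3 * d$x - 1.5 * d$w
  fit <- ols_fit(d, "y", c("x", "w"))
  expect_equal(unname(fit$coefficients), c(2, 3, -1.5), tolerance = 1e-10)
  expect_equal(fit$residual_variance, 0, tolerance = 1e-18)
  expect_error(ols_fit(d[1:3, ], "y", c("x", "w")), "insufficient")
  d$x2 <- 2 * d$x
  expect_error(ols_fit(d, "y", c("x", "x2")), "singular")

  big <- simulate_complete(fig1(), 1e5, seed = 31)
  f1 <- ols_fit(big, "Y", "X")
  expect_lt(abs(f1$coefficients[["X"]] - 1), 4 * sqrt(f1$vcov["X", "X"]))
  f3 <- ols_fit(big, "Y", c("X", "W", "R"))
  expect_lt(abs(f3$coefficients[["X"]] - 1.2), 4 * sqrt(f3$vcov["X", "X"]))
})

test_that("Rubin pooling matches hand arithmetic and its identity", {
  p <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(p$pooled_estimate, 2)
  expect_equal(p$within_var, 1)
  expect_equal(p$between_var, 2)
  expect_equal(p$total_var, 4)
  expect_equal(p$se, 2)
  # degenerate: identical estimates
  p0 <- pool_rubin(c(1.5, 1.5, 1.5), c(0.2, 0.3, 0.4))
  expect_equal(p0$between_var, 0)
  expect_equal(p0$total_var, p0$within_var)
  expect_identical(p0$dof, Inf)
  expect_error(pool_rubin(1, 1), "at least 2")
  expect_error(pool_rubin(c(1, 2), 1), "equal length")
  # identity T = W + (1 + 1/m) B over random inputs
  set.seed(606)
  for (k in 1:50) {
    m <- sample(2:30, 1)
    p <- pool_rubin(stats::rnorm(m), stats::rchisq(m, 3))
    expect_equal(p$total_var,
                 p$within_var + (1 + 1 / p$m) * p$between_var)
    expect_equal(p$se, sqrt(p$total_var))
  }
})

test_that("proper imputation is reproducible and validates its inputs", {
  d <- simulate_complete(fig1(), 400, seed = 37)
  d <- impose_missingness(d, missingness_spec("Y", pi0 = 0.5))
  i1 <- impute_normal(d, "Y", c("X", "W"), m = 3, seed = 5)
  i2 <- impute_normal(d, "Y", c("X", "W"), m = 3, seed = 5)
  expect_identical(i1, i2)
  expect_length(i1, 3)
  expect_false(anyNA(i1[[2]]$Y))
  # observed entries are never altered
  obs <- !is.na(d$Y)
  expect_equal(i1[[1]]$Y[obs], d$Y[obs])
  # nothing to impute is an error, not a silent no-op
  full <- simulate_complete(fig1(), 100, seed = 38)
  expect_error(impute_normal(full, "Y", "X", m = 2, seed = 1),
               "no missing")
  dd <- d; dd$X[1] <- NA
  expect_error(impute_normal(dd, "Y", c("X", "W"), m = 2, seed = 1),
               "fully observed")
  expect_error(impute_normal(d, "Y", "X", m = 1, seed = 1), "at least 2")
})

test_that("binary imputation preserves observed entries and binariness", {
  d <- simulate_complete(fig1(), 800, seed = 39)
  d <- dichotomize(d, "Y", prevalence = 0.4)
  d$Y[d$R > stats::quantile(d$R, 0.6)] <- NA
  imp <- impute_binary(d, "Y", c("X", "W"), m = 4, seed = 2)
  expect_length(imp, 4)
  for (cd in imp) expect_true(all(cd$Y %in% c(0L, 1L)))
  obs <- !is.na(d$Y)
  expect_equal(imp[[3]]$Y[obs], d$Y[obs])
})

test_that("MI with only the exposure recovers nothing beyond CRA", {
  m <- fig1()
  diffs <- vapply(1:150, function(r) {
    rr <- colliderMI:::.mi_rep(m, 0.5, 400, 20, "Y", "X", "Y", "X",
                               colliderMI:::.rep_seed(71, r))
    rr[["mi"]] - rr[["cra"]]
  }, 0)
  expect_lt(abs(mean(diffs)), 4 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("valid-MAR MI is unbiased and its intervals are calibrated", {
  m <- fig1()
  rr <- colliderMI:::.run_reps(m, 0.3, 700, 600, 20, "Y", c("X", "Z", "W"),
                               "Y", "X", 23)
  bias <- mean(rr[, "mi"]) - 1
  expect_lt(abs(bias), 4 * stats::sd(rr[, "mi"]) / sqrt(nrow(rr)))
  cover <- mean(abs(rr[, "mi"] - 1) <=
                  stats::qt(0.975, rr[, "mi_dof"]) * sqrt(rr[, "mi_var"]))
  expect_gte(cover, 0.92)
  expect_lte(cover, 0.98)
})

test_that("CRA is unbiased in the outcome scenario but not when the
           outcome drives exposure missingness", {
  m1 <- fig1()
  rr1 <- colliderMI:::.run_reps(m1, 0.5, 500, 500, 2, "Y", c("X", "W"),
                                "Y", "X", 83)
  expect_lt(abs(mean(rr1[, "cra"]) - 1),
            4 * stats::sd(rr1[, "cra"]) / sqrt(nrow(rr1)))
  m6 <- path_model_preset("fig6")
  rr6 <- colliderMI:::.run_reps(m6, 0.5, 500, 500, 2, "X", c("Y", "W"),
                                "Y", "X", 89)
  expect_gt(abs(mean(rr6[, "cra"]) - 1),
            6 * stats::sd(rr6[, "cra"]) / sqrt(nrow(rr6)))
})

test_that("the fast replicate engine agrees with the reference MI route", {
  m <- fig1()
  nr <- 120
  fast <- t(vapply(1:nr, function(r) {
    colliderMI:::.mi_rep(m, 0.5, 300, 20, "Y", c("X", "W"), "Y", "X",
                         colliderMI:::.rep_seed(97, r))
  }, numeric(7)))
  slow <- t(vapply(1:nr, function(r) {
    d <- simulate_complete(m, 600, seed = colliderMI:::.rep_seed(98, r))
    d <- impose_missingness(d, missingness_spec("Y", pi0 = 0.5,
                                                calibration = "empirical"))
    f <- mi_analyze(d, "Y", "X", "Y", c("X", "W"), m = 20,
                    seed = colliderMI:::.rep_seed(99, r))
    c(f$pooled_estimate, f$total_var, f$alpha1_obs)
  }, numeric(3)))
  # same distribution: means agree within Monte-Carlo error, and the
  # Rubin variances track the replicate variance on both routes
  se_pair <- sqrt(stats::var(fast[, "mi"]) / nr + stats::var(slow[, 1]) / nr)
  expect_lt(abs(mean(fast[, "mi"]) - mean(slow[, 1])), 4 * se_pair)
  expect_lt(abs(mean(fast[, "mi_var"]) / mean(slow[, 2]) - 1), 0.25)
  expect_lt(abs(mean(fast[, "alpha1_obs"]) - mean(slow[, 3])),
            4 * se_pair)
})

test_that("mi_analyze pools per-imputation fits and records alpha1", {
  d <- simulate_complete(fig1(), 500, seed = 41)
  d <- impose_missingness(d, missingness_spec("Y", pi0 = 0.4))
  res <- mi_analyze(d, "Y", "X", "Y", c("X", "W"), m = 10, seed = 6)
  expect_s3_class(res, "mi_result")
  expect_length(res$per_imputation_estimates, 10)
  expect_equal(res$total_var,
               res$within_var + (1 + 1 / 10) * res$between_var)
  manual_a1 <- ols_fit(d, "Y", c("X", "W"))$coefficients[["X"]]
  expect_equal(res$alpha1_obs, manual_a1)
  # CRA on full data equals plain OLS when nothing is missing
  full <- simulate_complete(fig1(), 300, seed = 43)
  expect_equal(cra_estimate(full, "Y", "X")$estimate,
               ols_fit(full, "Y", "X")$coefficients[["X"]])
})
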
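test_that("maximum bias of the outcome case matches hand arithmetic", {
  expect_equal(max_bias_outcome(fig1()), 0.2)
  expect_equal(max_bias_outcome(fig1(coefficients = c("Y~Z" = 0))), 0)
  expect_equal(max_bias_outcome(fig1(coefficients = c("R~X" = -1))), -0.2)
  expect_error(max_bias_outcome(path_model_preset("fig4")), "structure")
})

test_that("the direct-effects formula and the conditional-moments bound agree", {
  b <- bias_bound(fig1())
  expect_equal(unname(b), c(0, 0.2))
  expect_equal(unname(bias_bound(fig1(coefficients = c("W~U" = 0)))),
               c(0, 0), tolerance = 1e-12)
  # dual-route equivalence over randomized models
  set.seed(101)
  for (k in 1:120) {
    m <- random_fig1()
    expect_equal(unname(bias_bound(m)["upper"]), abs(max_bias_outcome(m)),
                 tolerance = 1e-8)
  }
})

test_that("maximum bias is invariant to the exposure-outcome effect", {
  set.seed(202)
  for (k in 1:30) {
    m <- random_fig1()
    vals <- vapply(c(-2, 0, 2), function(b) {
      max_bias_outcome(.set_yx(m, b))
    }, 0)
    expect_equal(vals[1], vals[2], tolerance = 1e-12)
    expect_equal(vals[2], vals[3], tolerance = 1e-12)
  }
})

test_that("sign rule and zero-factor law hold", {
  set.seed(303)
  key <- c("R~X", "R~U", "W~U", "Y~Z", "W~Z")
  for (k in 1:100) {
    m <- random_fig1()
    prod5 <- m$B["R", "X"] * m$B["R", "U"] * m$B["W", "U"] *
      m$B["Y", "Z"] * m$B["W", "Z"]
    expect_equal(sign(max_bias_outcome(m)), sign(prod5))
  }
  for (edge in key) {
    co <- stats::setNames(0, edge)
    expect_identical(max_bias_outcome(fig1(coefficients = co)), 0)
  }
})

test_that("covariance-form maximum bias reproduces worked values", {
  s <- summary_stats(var_x = 0.228, var_w = 0.286, cov_yw = 0.171,
                     logor_x_r = log(2.31), logor_w_r = log(1.15))
  expect_equal(round(max_bias_covform(s), 3), 0.008)
  s0 <- summary_stats(0.228, 0.286, 0.171, log(2.31), 0)
  expect_equal(max_bias_covform(s0), 0)
  # equivalence with the direct-effects formula, R standardized
  expect_equal(max_bias_covform(summary_stats_from_model(fig1())), 0.2)
  set.seed(404)
  for (k in 1:60) {
    m <- random_fig1()
    expect_equal(max_bias_covform(summary_stats_from_model(m)),
                 max_bias_outcome(m), tolerance = 1e-8)
  }
})

test_that("covariance form flags its invalid regime", {
  s <- summary_stats(var_x = 0.2, var_w = 0.2, cov_yw = 0.1,
                     logor_x_r = 12, logor_w_r = 1)
  expect_error(max_bias_covform(s), "denominator")
})

test_that("exposure-case imputation coefficient bias matches hand values", {
  expect_equal(max_bias_exposure_alpha1(path_model_preset("fig4")), -1 / 104)
  expect_equal(
    max_bias_exposure_alpha1(path_model_preset("fig4",
                                               coefficients = c("W~U" = 0))),
    0)
  expect_equal(
    max_bias_exposure_alpha1(path_model_preset("fig4",
                                               coefficients = c("X~Z" = 0))),
    0, tolerance = 1e-12)
  expect_error(max_bias_exposure_alpha1(fig1()), "structure")
})

test_that("standard-error profile reproduces the endpoint formulas", {
  p <- se_profile(fig1(), n_observed = 1000)
  expect_equal(p$se_mi_at_0, sqrt(5 / 3 / 1000), tolerance = 1e-10)
  expect_equal(p$se_cra_at_0, sqrt(2 / 1000), tolerance = 1e-10)
  expect_equal(p$se_mi_limit, sqrt(1.6 / (1000 * 0.625)), tolerance = 1e-10)
  expect_equal(p$se_cra_limit, sqrt(2 / (1000 * 2 / 3)), tolerance = 1e-10)
  expect_equal(p$relative_precision_pct,
               relative_precision(p$se_mi_limit, p$se_cra_limit))
  expect_equal(round(p$relative_precision_pct, 1), 14.7)
  expect_error(se_profile(fig1(), 1), "at least 2")
})

test_that("CRA standard error never shrinks as missingness grows", {
  set.seed(505)
  for (k in 1:50) {
    p <- se_profile(random_fig1(), n_observed = 500)
    expect_gte(p$se_cra_limit, p$se_cra_at_0 - 1e-12)
  }
})

test_that("profile reduces to the unadjusted SE when the collider is
           uninformative", {
  m <- fig1(coefficients = c("Y~Z" = 0))  # Cov(Y, W) = 0
  p <- se_profile(m, 1000)
  expect_equal(p$se_mi_at_0, p$se_cra_at_0, tolerance = 1e-12)
})

test_that("logit-probit conversion is the 0.6 rule with exact round trip", {
  expect_equal(probit_from_logor(log(2.31)), 0.6 * log(2.31))
  expect_equal(round(probit_from_logor(log(2.31)), 3), 0.502)
  expect_equal(exp(logor_from_probit(0)), 1)
  expect_equal(round(exp(logor_from_probit(0.5)), 2), 2.30)
  x <- c(-1.3, 0, 0.42, 2)
  expect_equal(probit_from_logor(logor_from_probit(x)), x)
  expect_equal(logor_from_probit(probit_from_logor(x, 0.59), 0.59), x)
})

test_that("relative precision is the variance-ratio complement", {
  expect_equal(relative_precision(1, 1), 0)
  expect_equal(relative_precision(sqrt(0.5), 1), 50)
  expect_equal(round(relative_precision(0.0506, 0.0548), 1), 14.7)
  expect_error(relative_precision(0, 1), "positive")
})
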
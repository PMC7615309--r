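test_that("simulation is reproducible and respects the generating model", {
  m <- fig1()
  d1 <- simulate_complete(m, 200, seed = 7)
  d2 <- simulate_complete(m, 200, seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate_complete(m, 200, seed = 8)
  expect_false(identical(d1$Y, d3$Y))
  expect_error(simulate_complete(m, 0, seed = 1), "at least 1")
  # degenerate error variance pins the structural equation
  md <- fig1(error_variances = c(Y = 1e-12))
  dd <- simulate_complete(md, 100, seed = 3)
  expect_equal(dd$Y, dd$X + dd$Z, tolerance = 1e-4)
})

test_that("upstream draws are unchanged when a downstream variable is added", {
  m_full <- fig1()
  m_noR <- path_model(
    c("X", "Z", "U", "Y", "W", "RR"),
    data.frame(child = c("Y", "Y", "W", "W"),
               parent = c("X", "Z", "Z", "U")),
    roles = c(outcome = "Y", exposure = "X", predictor = "Z",
              collider = "W", unmeasured = "U", missingness = "RR"))
  a <- simulate_complete(m_full, 100, seed = 11)
  b <- simulate_complete(m_noR, 100, seed = 11)
  for (v in c("X", "Z", "U", "Y", "W")) expect_equal(a[[v]], b[[v]])
})

test_that("simulated covariances converge to the implied moments", {
  n <- 1e5
  for (preset in c("fig1", "fig4", "fig6", "fig8-theoretical")) {
    m <- path_model_preset(preset)
    j <- implied_moments(m)
    d <- as.matrix(as.data.frame(simulate_complete(m, n, seed = 13)))
    emp <- stats::cov(d)
    for (a in m$variables) for (b in m$variables) {
      tol <- 4 * cov_mc_se(j$sigma[a, a], j$sigma[b, b], j$sigma[a, b], n)
      expect_lt(abs(emp[a, b] - j$sigma[a, b]), tol)
    }
  }
})

test_that("dichotomize thresholds at the implied quantile", {
  m <- fig1()
  d <- simulate_complete(m, 1e5, seed = 17)
  d5 <- dichotomize(d, "X", prevalence = 0.5)
  expect_equal(attr(d5, "thresholds")$X, 0)
  expect_setequal(unique(d5$X), c(0L, 1L))
  d3 <- dichotomize(d, "W", prevalence = 0.3)
  expect_lt(abs(mean(d3$W) - 0.3), 4 * sqrt(0.3 * 0.7 / 1e5))
  expect_warning(dichotomize(d, "Z", prevalence = 0.001), "close to 0 or 1")
  expect_error(dichotomize(d, "Z", prevalence = 1.2), "between 0 and 1")
})

test_that("probit missingness is calibrated through the latent R", {
  m <- fig1()
  d <- simulate_complete(m, 1e5, seed = 19)
  # no missingness requested: nothing masked
  d0 <- impose_missingness(d, missingness_spec("Y", pi0 = 0))
  expect_false(anyNA(d0$Y))
  expect_true(all(d0$R_ind == 1))
  # theoretical threshold for pi0 = 0.3085: sqrt(3) * qnorm(0.6915)
  d1 <- impose_missingness(d, missingness_spec("Y", pi0 = 0.3085))
  expect_equal(attr(d1, "missingness")$threshold,
               sqrt(3) * stats::qnorm(0.6915), tolerance = 1e-6)
  expect_equal(round(attr(d1, "missingness")$threshold, 3), 0.866)
  # realized missing fraction
  d2 <- impose_missingness(d, missingness_spec("Y", pi0 = 0.5))
  expect_lt(abs(mean(is.na(d2$Y)) - 0.5), 4 * sqrt(0.25 / 1e5))
  expect_equal(is.na(d2$Y), d2$R_ind == 0)
  # empirical calibration fixes the count exactly
  d3 <- impose_missingness(d, missingness_spec("Y", pi0 = 0.5,
                                               calibration = "empirical"))
  expect_equal(sum(is.na(d3$Y)), 5e4)
  expect_error(impose_missingness(d2, missingness_spec("Y", pi0 = 0.2)),
               "already has missing")
})

test_that("missingness is MAR given the exposure in the outcome scenario", {
  m <- fig1()
  d <- simulate_complete(m, 1e5, seed = 23)
  d <- impose_missingness(d, missingness_spec("Y", pi0 = 0.5))
  # among complete records, Y carries no information about R_ind once X
  # is conditioned on; fit on the pre-masking outcome values
  y_full <- simulate_complete(m, 1e5, seed = 23)$Y
  fit <- suppressWarnings(
    stats::glm(d$R_ind ~ y_full + d$X, family = stats::binomial()))
  z <- summary(fit)$coefficients["y_full", ]
  expect_lt(abs(z["Estimate"]), 4 * z["Std. Error"])
})

test_that("the synthetic cohort fixture matches its design targets", {
  d <- make_alspac_like(n = 12061, seed = 1)
  expect_equal(nrow(d), 12061)
  expect_lt(abs(mean(d$R_ind) - 0.60), 0.001)
  p <- mean(d$mated)
  expect_lt(abs(p * (1 - p) - 0.228), 0.01)
  expect_lt(abs(stats::var(d$bwt) - 0.286), 0.015)
  expect_equal(is.na(d$bmi7), d$R_ind == 0)
  expect_identical(attr(d, "latent"), c("U", "R"))
  expect_error(make_alspac_like(0), "at least 1")
  expect_error(make_alspac_like(100, 1, params = list(nope = 1)), "unknown")
})

test_that("CSV round trip is byte-identical under a fixed seed", {
  d <- make_alspac_like(n = 500, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(d, f1)
  write_study_csv(make_alspac_like(n = 500, seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_study_csv(f1)
  expect_equal(names(back), names(d))
  for (v in names(d)) {
    expect_equal(back[[v]], d[[v]], tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(sum(is.na(back$bmi7)), sum(is.na(d$bmi7)))
})
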
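# Child RNG stream per variable: a dataset-level seed plus a
# position-weighted hash of the variable name, so adding a variable
# downstream in the causal order does not perturb upstream draws.
.var_seed <- function(seed, varname) {
  h <- sum(utf8ToInt(varname) * (seq_along(utf8ToInt(varname)) * 131 + 7))
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + h) %% 2147483647)
}

# Matrix core shared by simulate_complete() and the Monte-Carlo harness.
.simulate_matrix <- function(model, n, seed) {
  vars <- model$variables  # topological order
  out <- matrix(0, n, length(vars), dimnames = list(NULL, vars))
  for (v in vars) {
    set.seed(.var_seed(seed, v))
    e <- stats::rnorm(n, 0, sqrt(model$error_variances[[v]]))
    pa <- names(which(model$B[v, ] != 0))
    val <- model$means[[v]] + e
    for (p in pa) val <- val + model$B[v, p] * out[, p]
    out[, v] <- val
  }
  out
}

#' Simulate complete subject-level data from a path model
#'
#' Draws `n` independent records: each variable equals its intercept plus
#' the linear combination of its parents plus a Gaussian error, generated
#' in topological order. Every variable is retained in the returned table,
#' including the unmeasured cause and the latent missingness variable;
#' those two are flagged as latent (see `attr(., "latent")`) and must not
#' be given to estimators as observed data.
#'
#' Randomness uses one child stream per variable, derived from `seed` and
#' the variable name, so the draws for a variable do not change when a
#' causally downstream variable is added to the model.
#'
#' @param model a [path_model()].
#' @param n number of records (>= 1).
#' @param seed integer seed.
#' @return a `study_dataset`: a `data.frame` with one column per model
#'   variable and attributes `model`, `seed`, and `latent` (names of the
#'   latent columns).
#' @export
#' @examples
#' d <- simulate_complete(path_model_preset("fig1"), n = 100, seed = 1)
#' head(d)
simulate_complete <- function(model, n, seed) {
  stopifnot(inherits(model, "path_model"))
  if (!is.numeric(n) || n < 1) stop("`n` must be at least 1")
  dat <- as.data.frame(.simulate_matrix(model, as.integer(n), seed))
  latent <- intersect(
    unname(model$roles[names(model$roles) %in% c("unmeasured", "missingness")]),
    model$variables)
  structure(dat, model = model, seed = seed, latent = latent,
            class = c("study_dataset", "data.frame"))
}

#' Dichotomize a continuous variable by latent-normal thresholding
#'
#' Replaces a continuous column by the indicator of exceeding the
#' `(1 - prevalence)` quantile of its implied marginal normal
#' distribution, so the indicator has expected prevalence `prevalence`.
#' Variables causally downstream were generated from the continuous
#' (latent) value, matching the underlying-normal argument under which
#' binary-variable results transfer from the continuous case.
#'
#' @param data a `study_dataset` from [simulate_complete()].
#' @param variable column to dichotomize.
#' @param prevalence target proportion of ones, in (0, 1). A warning is
#'   emitted for prevalences within 0.01 of the boundary, where the
#'   latent-normal correspondence degrades.
#' @param model path model supplying the implied marginal; defaults to the
#'   model stored in `data`.
#' @return the modified `study_dataset`; the latent threshold is recorded
#'   in `attr(., "thresholds")`.
#' @export
dichotomize <- function(data, variable, prevalence,
                        model = attr(data, "model")) {
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie strictly between 0 and 1")
  }
  if (min(prevalence, 1 - prevalence) < 0.01) {
    warning("probability of the binary variable is close to 0 or 1; ",
            "the latent-normal approximation degrades there")
  }
  if (!variable %in% names(data)) stop("unknown variable: ", variable)
  if (length(unique(data[[variable]])) <= 2) {
    stop("variable appears to be binary already: ", variable)
  }
  joint <- implied_moments(model)
  thr <- unname(joint$mean[variable] +
                  sqrt(joint$sigma[variable, variable]) *
                  stats::qnorm(1 - prevalence))
  data[[variable]] <- as.integer(data[[variable]] > thr)
  th <- attr(data, "thresholds")
  th[[variable]] <- thr
  attr(data, "thresholds") <- th
  data
}

#' Missingness specification
#'
#' Probit missingness through the latent variable `R`: a record's masked
#' entry is observed when its `R` value falls at or below a threshold `r`,
#' so the missingness proportion is `pi0 = P(R > r)`. Exactly one of
#' `pi0` or `threshold` is given. With `calibration = "theoretical"` the
#' threshold is set from the implied moments of `R`
#' (`r = mu_R + sqrt(V_R) * qnorm(1 - pi0)`), so `pi0` is exact in
#' expectation; `"empirical"` uses the realized `(1 - pi0)` quantile of
#' the simulated `R`, fixing the realized missing fraction.
#'
#' @param masked_variable name of the variable whose entries are masked.
#' @param pi0 target missingness proportion in `[0, 1]`.
#' @param threshold explicit threshold `r` (alternative to `pi0`).
#' @param calibration `"theoretical"` or `"empirical"`.
#' @return object of class `missingness_spec`.
#' @export
missingness_spec <- function(masked_variable, pi0 = NULL, threshold = NULL,
                             calibration = c("theoretical", "empirical")) {
  calibration <- match.arg(calibration)
  if (is.null(pi0) == is.null(threshold)) {
    stop("exactly one of `pi0` and `threshold` must be given")
  }
  if (!is.null(pi0) && (pi0 < 0 || pi0 > 1)) {
    stop("`pi0` must lie in [0, 1]")
  }
  structure(list(masked_variable = masked_variable, pi0 = pi0,
                 threshold = threshold, calibration = calibration),
            class = "missingness_spec")
}

#' Impose probit missingness through the latent variable R
#'
#' Adds the observation indicator `R_ind` (1 = observed) and masks the
#' specified variable where `R_ind = 0`, i.e. where the record's latent
#' `R` exceeds the threshold.
#'
#' @param data a `study_dataset` containing the latent `R` column.
#' @param spec a [missingness_spec()].
#' @param model path model supplying the implied moments of `R` for
#'   theoretical calibration; defaults to the model stored in `data`.
#' @return the modified `study_dataset`, with attribute `missingness`
#'   recording the spec and realized threshold.
#' @export
#' @examples
#' m <- path_model_preset("fig1")
#' d <- simulate_complete(m, 1000, seed = 1)
#' d <- impose_missingness(d, missingness_spec("Y", pi0 = 0.5))
#' mean(d$R_ind)
impose_missingness <- function(data, spec, model = attr(data, "model")) {
  stopifnot(inherits(spec, "missingness_spec"))
  v <- spec$masked_variable
  if (!v %in% names(data)) stop("unknown masked variable: ", v)
  if (anyNA(data[[v]])) {
    stop("masked variable already has missing entries: ", v)
  }
  R <- role_var(model, "missingness")
  if (!R %in% names(data)) {
    stop("latent missingness column `", R, "` not present in the data")
  }
  if (!is.null(spec$threshold)) {
    r <- spec$threshold
  } else if (spec$calibration == "theoretical") {
    joint <- implied_moments(model)
    r <- unname(joint$mean[R] + sqrt(joint$sigma[R, R]) *
                  stats::qnorm(1 - spec$pi0))
  } else {
    r <- unname(stats::quantile(data[[R]], 1 - spec$pi0, names = FALSE))
  }
  rind <- as.integer(data[[R]] <= r)
  data$R_ind <- rind
  data[[v]][rind == 0] <- NA_real_
  attr(data, "missingness") <- list(masked_variable = v, pi0 = spec$pi0,
                                    threshold = r,
                                    calibration = spec$calibration)
  data
}

#' Synthetic birth-cohort fixture with a collider auxiliary variable
#'
#' Generates a synthetic dataset emulating the structure of the applied
#' example: binary exposure `mated` (maternal post-16 education), continuous
#' outcome `bmi7` (child BMI at age 7, kg/m^2), binary direct predictor
#' `pregsize` (twin birth), continuous collider `bwt` (birth weight, kg), a
#' latent standard-normal common cause `U` (unmeasured, e.g. socioeconomic
#' position) and latent missingness variable `R`. Under the defaults about
#' 40% of `bmi7` values are masked, the exposure prevalence gives
#' `Var(mated) ~ 0.228` and `Var(bwt) ~ 0.286`, higher maternal education
#' strongly predicts an observed outcome, and `bwt` is a collider of
#' `bmi7` and its missingness (via `pregsize` and `U` respectively). `U`
#' also loads directly on `bmi7`, making it an unmeasured confounder of
#' the outcome-collider relationship and the outcome mildly
#' missing-not-at-random — the regime in which adjusting for the direct
#' predictor does not remove the collider bias and the MI estimate with
#' the collider is visibly attenuated.
#'
#' This generator is a synthetic stand-in: it reproduces the qualitative
#' structure (a collider auxiliary and education-driven missingness), not
#' the restricted cohort microdata.
#'
#' @param n number of records (default 12061).
#' @param seed integer seed.
#' @param params optional named list overriding any default parameter; see
#'   `colliderMI:::.alspac_defaults()` for names and values.
#' @return a `study_dataset` with columns `mated`, `pregsize`, `bwt`,
#'   `bmi7`, `U`, `R`, `R_ind`; `bmi7` is `NA` where `R_ind = 0`.
#' @export
#' @examples
#' d <- make_alspac_like(n = 2000, seed = 1)
#' mean(d$R_ind)
make_alspac_like <- function(n = 12061, seed = 1, params = NULL) {
  if (!is.numeric(n) || n < 1) stop("`n` must be at least 1")
  p <- .alspac_defaults()
  if (!is.null(params)) {
    if (length(bad <- setdiff(names(params), names(p)))) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(params)] <- params
  }
  n <- as.integer(n)
  draw <- function(v) { set.seed(.var_seed(seed, v)); stats::rnorm(n) }
  mated <- as.integer(draw("mated") > stats::qnorm(1 - p$prev_mated))
  pregsize <- as.integer(draw("pregsize") > stats::qnorm(1 - p$prev_twin))
  U <- draw("U")
  bwt <- p$bwt_intercept + p$bwt_mated * mated + p$bwt_twin * pregsize +
    p$bwt_u * U + p$bwt_sd * draw("bwt")
  bmi7 <- p$bmi_intercept + p$bmi_mated * mated + p$bmi_twin * pregsize +
    p$bmi_u * U + p$bmi_sd * draw("bmi7")
  R <- p$r_mated * mated + p$r_u * U + p$r_sd * draw("R")
  r_thr <- stats::quantile(R, 1 - p$pi0, names = FALSE)
  R_ind <- as.integer(R <= r_thr)
  bmi7[R_ind == 0] <- NA_real_
  dat <- data.frame(mated = mated, pregsize = pregsize, bwt = bwt,
                    bmi7 = bmi7, U = U, R = R, R_ind = R_ind)
  structure(dat, seed = seed, latent = c("U", "R"), params = p,
            missingness = list(masked_variable = "bmi7", pi0 = p$pi0,
                               threshold = r_thr, calibration = "empirical"),
            class = c("study_dataset", "data.frame"))
}

# Default generator parameters. Prevalences and scales are chosen as
# realistic cohort values: exposure prevalence 0.64 (binomial variance
# 0.230), twin births 2.6%, birth weight in kg around 3.42 with SD ~0.53,
# BMI at 7 in kg/m^2 around 16 with SD ~2, a small negative education
# effect on BMI, and 40% missing outcomes driven by education and U.
# U loads on birth weight, BMI and missingness: it is an unmeasured
# confounder of the outcome-collider relationship (so adjusting for the
# direct predictor does not neutralize the collider) and makes the
# outcome mildly missing-not-at-random, as judged plausible for the
# cohort this emulates.
.alspac_defaults <- function() {
  list(
    prev_mated = 0.64,   # exposure prevalence -> Var ~ 0.2304
    prev_twin = 0.026,   # twin-birth prevalence
    bwt_intercept = 3.42, bwt_mated = 0.05, bwt_twin = -0.91,
    bwt_u = 0.30, bwt_sd = sqrt(0.1745),   # total Var(bwt) ~ 0.286
    bmi_intercept = 16.1, bmi_mated = -0.11, bmi_twin = -0.45,
    bmi_u = 0.60, bmi_sd = 2,
    r_mated = -0.55, r_u = -0.40, r_sd = 1,  # education, U -> more observed
    pi0 = 0.40
  )
}

#' Write / read a study dataset as CSV with a JSON metadata sidecar
#'
#' CSV with a header row and empty fields for missing entries; the sidecar
#' `<path>.meta.json` records the seed, sample size, latent columns and
#' missingness metadata so a rewrite under the same seed is byte-identical.
#'
#' @param data a `study_dataset`.
#' @param path output CSV path.
#' @return `write_study_csv()`: `path`, invisibly. `read_study_csv()`: a
#'   `study_dataset`.
#' @export
write_study_csv <- function(data, path) {
  utils::write.table(as.data.frame(data), path, sep = ",", na = "",
                     row.names = FALSE, quote = FALSE)
  meta <- list(seed = attr(data, "seed"), n = nrow(data),
               latent = attr(data, "latent"),
               missingness = attr(data, "missingness"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  dat <- utils::read.csv(path, na.strings = "")
  metapath <- paste0(path, ".meta.json")
  meta <- if (file.exists(metapath)) jsonlite::read_json(metapath) else list()
  structure(dat, seed = meta$seed, latent = unlist(meta$latent),
            missingness = meta$missingness,
            class = c("study_dataset", "data.frame"))
}
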
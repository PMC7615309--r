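#' Screen candidate auxiliary variables for collider signatures
#'
#' Step 1 of the applied workflow. Given a user-declared causal ordering
#' of the observed variables (ending at the observation indicator), fits a
#' regression for each ordered pair — logistic when the dependent variable
#' is binary, linear otherwise — with the variables preceding the
#' explanatory variable as the adjustment set. For every candidate
#' auxiliary, the association with the observation indicator is refitted
#' conditioning additionally on each later variable (the candidate
#' collider); an association that strengthens upon conditioning is the
#' collider signature and raises a flag. The flag requires a material
#' strengthening — the absolute association must grow by at least half a
#' standard error of the conditional estimate — so that two noisy
#' near-null estimates do not trigger it.
#'
#' The ordering is a declared judgement about probable causal direction,
#' not something inferred from the data; only pairs consistent with it are
#' fitted.
#'
#' @param data a data frame containing the ordered variables and the
#'   observation indicator.
#' @param ordering character vector of variable names in causal order
#'   (earliest cause first), excluding the indicator.
#' @param rind name of the observation indicator column (1 = observed).
#' @return object of class `screen_table`: list with `pairs` (one row per
#'   fitted pair: explanatory, dependent, family, estimate, standard
#'   error, 95% CI, adjustment set, error message if the fit failed) and
#'   `collider_checks` (one row per auxiliary/candidate-collider
#'   combination: log odds ratios for the auxiliary-indicator association
#'   without and with the candidate, and the `strengthened` flag).
#' @export
#' @examples
#' d <- make_alspac_like(n = 3000, seed = 1)
#' screen_auxiliaries(d, c("mated", "pregsize", "bwt"))
screen_auxiliaries <- function(data, ordering, rind = "R_ind") {
  if (length(bad <- setdiff(c(ordering, rind), names(data)))) {
    stop("unknown variable(s) in ordering: ", paste(bad, collapse = ", "))
  }
  is_bin <- function(v) length(unique(stats::na.omit(data[[v]]))) <= 2
  fit_pair <- function(dep, expl, adjust) {
    rhs <- paste(c(expl, adjust), collapse = " + ")
    fml <- stats::as.formula(paste(dep, "~", rhs))
    fam <- if (is_bin(dep)) "logistic" else "linear"
    res <- tryCatch({
      if (length(unique(stats::na.omit(data[[dep]]))) < 2) {
        stop("dependent variable has zero variance")
      }
      fit <- if (fam == "logistic") {
        suppressWarnings(stats::glm(fml, data = data, family = stats::binomial()))
      } else {
        stats::lm(fml, data = data)
      }
      sm <- summary(fit)$coefficients
      est <- sm[expl, 1]; se <- sm[expl, 2]
      list(est = est, se = se, err = NA_character_)
    }, error = function(e) {
      list(est = NA_real_, se = NA_real_, err = conditionMessage(e))
    })
    data.frame(explanatory = expl, dependent = dep, family = fam,
               estimate = res$est, se = res$se,
               ci_low = res$est - 1.96 * res$se,
               ci_high = res$est + 1.96 * res$se,
               adjusted_for = paste(adjust, collapse = ","),
               error = res$err, stringsAsFactors = FALSE)
  }

  seq_vars <- c(ordering, rind)
  pairs <- list()
  for (j in seq_along(seq_vars)[-1]) {
    for (i in seq_len(j - 1)) {
      expl <- seq_vars[i]; dep <- seq_vars[j]
      adjust <- if (i > 1) seq_vars[seq_len(i - 1)] else character(0)
      pairs[[length(pairs) + 1]] <- fit_pair(dep, expl, adjust)
    }
  }
  pairs <- do.call(rbind, pairs)

  checks <- list()
  for (i in seq_along(ordering)) {
    aux <- ordering[i]
    adjust <- if (i > 1) ordering[seq_len(i - 1)] else character(0)
    base <- fit_pair(rind, aux, adjust)
    for (w in ordering[-seq_len(i)]) {
      cond <- fit_pair(rind, aux, c(adjust, w))
      # flag only a material strengthening: the association must move away
      # from zero by at least half a standard error of the conditional
      # estimate, so two noisy near-null estimates do not raise the flag
      strengthened <- !is.na(base$estimate) && !is.na(cond$estimate) &&
        (abs(cond$estimate) - abs(base$estimate)) > 0.5 * cond$se
      checks[[length(checks) + 1]] <- data.frame(
        auxiliary = aux, conditioned_on = w,
        logor_unadjusted = base$estimate, logor_conditional = cond$estimate,
        conditional_se = cond$se,
        strengthened = strengthened, stringsAsFactors = FALSE)
    }
  }
  checks <- if (length(checks)) do.call(rbind, checks) else
    data.frame(auxiliary = character(0), conditioned_on = character(0),
               logor_unadjusted = numeric(0), logor_conditional = numeric(0),
               conditional_se = numeric(0), strengthened = logical(0))
  structure(list(pairs = pairs, collider_checks = checks,
                 ordering = ordering, rind = rind),
            class = "screen_table")
}

#' @export
print.screen_table <- function(x, digits = 3, ...) {
  cat("Auxiliary-variable screen (ordering:",
      paste(x$ordering, collapse = " -> "), "->", x$rind, ")\n\n")
  pr <- x$pairs
  pr$estimate <- round(pr$estimate, digits)
  pr$se <- round(pr$se, digits)
  pr$ci_low <- round(pr$ci_low, digits); pr$ci_high <- round(pr$ci_high, digits)
  print(pr[, c("explanatory", "dependent", "family", "estimate", "se",
               "ci_low", "ci_high", "adjusted_for")], row.names = FALSE)
  if (nrow(x$collider_checks)) {
    cat("\nCollider signatures (association with", x$rind,
        "upon conditioning):\n")
    cc <- x$collider_checks
    cc$logor_unadjusted <- round(cc$logor_unadjusted, digits)
    cc$logor_conditional <- round(cc$logor_conditional, digits)
    print(cc, row.names = FALSE)
  }
  invisible(x)
}

#' Estimate plug-in summary statistics from a partially observed dataset
#'
#' Computes the [summary_stats()] inputs of the covariance-form
#' maximum-bias formula from subject-level data: the exposure variance by
#' the binomial formula `p(1-p)` when the exposure is binary (sample
#' variance otherwise), the collider variance from all records, the
#' outcome-collider covariance from complete records only, and the log
#' odds ratios from logistic regressions of the observation indicator on
#' the exposure (marginal) and on the collider (adjusted for the
#' exposure).
#'
#' @param data a data frame.
#' @param roles named character vector assigning `outcome`, `exposure`,
#'   `collider` to column names.
#' @param rind name of the observation indicator column; derived from the
#'   outcome's missingness when the column is absent.
#' @return a [summary_stats()].
#' @export
estimate_summary_stats <- function(data, roles, rind = "R_ind") {
  for (need in c("outcome", "exposure", "collider")) {
    if (!need %in% names(roles)) stop("roles must assign `", need, "`")
  }
  Y <- roles[["outcome"]]; X <- roles[["exposure"]]; W <- roles[["collider"]]
  if (length(bad <- setdiff(c(Y, X, W), names(data)))) {
    stop("unknown variable(s): ", paste(bad, collapse = ", "))
  }
  y <- data[[Y]]
  if (!anyNA(y)) {
    stop("the outcome has no missing values; the observation-indicator ",
         "log odds ratios are undefined")
  }
  if (all(is.na(y))) stop("the outcome is entirely missing")
  x <- data[[X]]; w <- data[[W]]
  # derive the observation indicator from the outcome when not supplied
  r <- if (rind %in% names(data)) data[[rind]] else as.integer(!is.na(y))
  var_x <- if (length(unique(stats::na.omit(x))) <= 2) {
    p <- mean(x, na.rm = TRUE); p * (1 - p)
  } else stats::var(x, na.rm = TRUE)
  var_w <- stats::var(w, na.rm = TRUE)
  cc <- stats::complete.cases(y, w)
  cov_yw <- stats::cov(y[cc], w[cc])
  logor_x <- stats::coef(suppressWarnings(
    stats::glm(r ~ x, family = stats::binomial())))[["x"]]
  logor_w <- stats::coef(suppressWarnings(
    stats::glm(r ~ w + x, family = stats::binomial())))[["w"]]
  summary_stats(var_x = var_x, var_w = var_w, cov_yw = cov_yw,
                logor_x_r = logor_x, logor_w_r = logor_w, w_adjusted = TRUE)
}

#' Plug-in maximum bias with an approximate confidence interval
#'
#' Step 2 of the applied workflow: evaluates the covariance-form maximum
#' bias and attaches the approximate interval
#' `max_bias +/- multiplier * se_reference`, where `se_reference` is the
#' standard error of the MI estimate that includes the collider (treating
#' the true exposure coefficient as fixed).
#'
#' @param stats a [summary_stats()].
#' @param se_reference positive reference standard error.
#' @param ci_multiplier interval multiplier (default 1.96).
#' @param estimate optional analysis estimate of the exposure coefficient,
#'   used to annotate whether the bias points towards or away from the
#'   null.
#' @return object of class `plugin_bias`: list with `max_bias`,
#'   `se_reference`, `ci_low`, `ci_high`, `direction_note`, `inputs`.
#' @export
#' @examples
#' s <- summary_stats(0.228, 0.286, 0.171, log(2.31), log(1.15))
#' plugin_max_bias(s, se_reference = 0.047, estimate = -0.108)
plugin_max_bias <- function(stats, se_reference, ci_multiplier = 1.96,
                            estimate = NULL) {
  if (!is.numeric(se_reference) || se_reference <= 0) {
    stop("`se_reference` must be positive")
  }
  mb <- max_bias_covform(stats)
  note <- if (is.null(estimate) || mb == 0) {
    NA_character_
  } else if (sign(mb) != sign(estimate)) {
    "towards the null"
  } else {
    "away from the null"
  }
  if (isTRUE(stats$w_adjusted)) {
    note <- paste(stats::na.omit(c(note,
      "collider log odds ratio estimated conditional on the exposure, substituted for the marginal covariance")),
      collapse = "; ")
  }
  structure(list(max_bias = mb, se_reference = se_reference,
                 ci_low = mb - ci_multiplier * se_reference,
                 ci_high = mb + ci_multiplier * se_reference,
                 direction_note = note, inputs = stats),
            class = "plugin_bias")
}

#' @export
print.plugin_bias <- function(x, digits = 3, ...) {
  cat(sprintf("Plug-in maximum bias: %.*f (95%% CI %.*f to %.*f)\n",
              digits, x$max_bias, digits, x$ci_low, digits, x$ci_high))
  if (!is.na(x$direction_note)) cat("  note:", x$direction_note, "\n")
  invisible(x)
}

#' Compare missing-data analysis strategies on one dataset
#'
#' Fits the analysis model under complete-records analysis and under MI
#' with each requested auxiliary-variable set, mirroring the applied
#' comparison table: one row per strategy with estimate, standard error
#' and 95% confidence interval. Every imputation model includes the
#' analysis exposure; `"MI+Z"`, `"MI+W"`, `"MI+Z+W"` add the direct
#' predictor, the collider, or both.
#'
#' @param data a data frame with a partially observed outcome.
#' @param roles named character vector assigning `outcome`, `exposure`,
#'   and as needed `predictor` (Z) and `collider` (W) to column names.
#' @param strategies subset of `c("CRA", "MI", "MI+Z", "MI+W", "MI+Z+W")`.
#' @param m imputations per MI strategy.
#' @param seed integer seed.
#' @return data frame with columns `strategy`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `m`.
#' @export
#' @examples
#' d <- make_alspac_like(n = 3000, seed = 1)
#' compare_strategies(d,
#'   roles = c(outcome = "bmi7", exposure = "mated",
#'             predictor = "pregsize", collider = "bwt"),
#'   m = 10, seed = 2)
compare_strategies <- function(data, roles,
                               strategies = c("CRA", "MI", "MI+Z", "MI+W",
                                              "MI+Z+W"),
                               m = 100, seed = 1) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  Y <- roles[["outcome"]]; X <- roles[["exposure"]]
  Z <- roles["predictor"]; W <- roles["collider"]
  aux <- list("MI" = character(0),
              "MI+Z" = unname(Z), "MI+W" = unname(W),
              "MI+Z+W" = unname(c(Z, W)))
  no_missing <- !anyNA(data[[Y]])
  rows <- lapply(strategies, function(s) {
    if (s == "CRA" || no_missing) {
      fit <- cra_estimate(data, Y, X)
      data.frame(strategy = s, estimate = fit$estimate, se = fit$se,
                 ci_low = fit$ci[1], ci_high = fit$ci[2], m = NA_integer_)
    } else {
      preds <- c(X, aux[[s]])
      if (anyNA(preds)) {
        stop("strategy ", s, " needs roles for its auxiliary variables")
      }
      fit <- mi_analyze(data, response = Y, predictors = X,
                        imp_target = Y, imp_predictors = preds,
                        m = m, seed = seed)
      data.frame(strategy = s, estimate = fit$pooled_estimate, se = fit$se,
                 ci_low = fit$ci[1], ci_high = fit$ci[2], m = m)
    }
  })
  do.call(rbind, rows)
}
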
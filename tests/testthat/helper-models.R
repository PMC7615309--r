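# Shared fixtures: presets and randomized outcome-missing models.

fig1 <- function(...) path_model_preset("fig1", ...)

# Random fig1-shaped model: coefficients in [-2, 2], error variances in
# [0.25, 4]. Used by the dual-route and sign/zero property suites.
random_fig1 <- function() {
  coefs <- stats::runif(6, -2, 2)
  names(coefs) <- c("Y~X", "Y~Z", "W~Z", "W~U", "R~X", "R~U")
  evs <- stats::runif(6, 0.25, 4)
  names(evs) <- c("X", "Z", "U", "Y", "W", "R")
  path_model_preset("fig1", coefficients = coefs, error_variances = evs)
}

# Replace the exposure-outcome path coefficient in place.
.set_yx <- function(model, value) {
  model$B["Y", "X"] <- value
  model
}

# Monte-Carlo standard error of a sample covariance between components
# with variances vii, vjj and covariance vij.
cov_mc_se <- function(vii, vjj, vij, n) sqrt((vii * vjj + vij^2) / n)
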
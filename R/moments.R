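#' Exact implied moments of a path model
#'
#' Computes the joint Gaussian distribution implied by a linear path model
#' in closed form via the reduced-form map from the exogenous errors:
#' writing the structural system as `x = nu + B x + e` with
#' `e ~ N(0, diag(sigma^2))`, the implied moments are
#' `mu = (I - B)^{-1} nu` and `Sigma = (I - B)^{-1} diag(sigma^2) (I - B)^{-T}`.
#' All variables are included, in particular the unmeasured cause `U` and
#' the latent missingness variable `R`.
#'
#' @param model a [path_model()].
#' @return an object of class `joint_gaussian`: list with `variables`,
#'   `mean` (named vector) and `sigma` (covariance matrix with dimnames).
#' @export
#' @examples
#' implied_moments(path_model_preset("fig1"))
implied_moments <- function(model) {
  stopifnot(inherits(model, "path_model"))
  k <- length(model$variables)
  A <- solve(diag(k) - model$B)
  sigma <- A %*% diag(model$error_variances, k) %*% t(A)
  sigma <- (sigma + t(sigma)) / 2
  dimnames(sigma) <- list(model$variables, model$variables)
  mu <- drop(A %*% model$means)
  names(mu) <- model$variables
  joint_gaussian(model$variables, mu, sigma)
}

#' Construct a joint Gaussian distribution
#'
#' Container for a mean vector and covariance matrix over named variables.
#' The covariance matrix is validated to be symmetric and positive
#' semi-definite up to a relative tolerance of `1e-10` on the largest
#' eigenvalue.
#'
#' @param variables character vector of names.
#' @param mean numeric mean vector.
#' @param sigma covariance matrix.
#' @return object of class `joint_gaussian`.
#' @export
joint_gaussian <- function(variables, mean, sigma) {
  k <- length(variables)
  sigma <- as.matrix(sigma)
  if (length(mean) != k || !all(dim(sigma) == k)) {
    stop("dimension of mean/covariance does not match the variable list")
  }
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stop("covariance matrix is not symmetric")
  }
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev))) {
    stop("covariance matrix is not positive semi-definite")
  }
  dimnames(sigma) <- list(variables, variables)
  names(mean) <- variables
  structure(list(variables = variables, mean = mean, sigma = sigma),
            class = "joint_gaussian")
}

#' @export
print.joint_gaussian <- function(x, digits = 4, ...) {
  cat("Joint Gaussian over:", paste(x$variables, collapse = ", "), "\n")
  cat("mean:\n"); print(round(x$mean, digits))
  cat("covariance:\n"); print(round(x$sigma, digits))
  invisible(x)
}

#' Population regression implied by a joint Gaussian
#'
#' Gaussian conditioning: the population least-squares regression of
#' `target` on `predictors`, with coefficients
#' `b = Sigma_pp^{-1} sigma_pt`, intercept `mu_t - b' mu_p` and residual
#' variance `sigma_tt - sigma_tp b`. With an empty predictor set the
#' residual variance is the marginal variance of the target.
#'
#' @param joint a [joint_gaussian()] (or a [path_model()], in which case
#'   [implied_moments()] is applied first).
#' @param target name of the dependent variable.
#' @param predictors character vector of predictor names (may be empty).
#' @return object of class `conditional_model`: list with `target`,
#'   `predictors`, `intercept`, `coefficients` (named) and
#'   `residual_variance`.
#' @export
#' @examples
#' j <- implied_moments(path_model_preset("fig1"))
#' conditional_regression(j, "Y", c("X", "W"))     # slope on X is 1
#' conditional_regression(j, "Y", c("X", "W", "R")) # slope on X is 1.2
conditional_regression <- function(joint, target, predictors = character(0)) {
  if (inherits(joint, "path_model")) joint <- implied_moments(joint)
  stopifnot(inherits(joint, "joint_gaussian"))
  vars <- joint$variables
  if (!target %in% vars) stop("unknown target variable: ", target)
  if (length(bad <- setdiff(predictors, vars))) {
    stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  }
  if (target %in% predictors) stop("target cannot be one of the predictors")
  s_tt <- joint$sigma[target, target]
  if (!length(predictors)) {
    return(structure(
      list(target = target, predictors = character(0), intercept =
             unname(joint$mean[target]), coefficients = numeric(0),
           residual_variance = unname(s_tt)),
      class = "conditional_model"))
  }
  S_pp <- joint$sigma[predictors, predictors, drop = FALSE]
  s_pt <- joint$sigma[predictors, target]
  b <- tryCatch(solve(S_pp, s_pt), error = function(e) {
    stop("singular predictor covariance (collinear predictors): ",
         conditionMessage(e))
  })
  names(b) <- predictors
  rv <- unname(s_tt - sum(s_pt * b))
  rv <- max(rv, 0)  # guard tiny negative round-off
  structure(
    list(target = target, predictors = predictors,
         intercept = unname(joint$mean[target] -
                              sum(b * joint$mean[predictors])),
         coefficients = b, residual_variance = rv),
    class = "conditional_model")
}

#' @export
print.conditional_model <- function(x, digits = 4, ...) {
  cat(x$target, "~",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ")
      else "1", "\n")
  cat("intercept:", round(x$intercept, digits), "\n")
  if (length(x$coefficients)) {
    cat("coefficients:\n"); print(round(x$coefficients, digits))
  }
  cat("residual variance:", round(x$residual_variance, digits), "\n")
  invisible(x)
}

# Conditional covariance Cov(a, b | given) from a joint_gaussian.
cond_cov <- function(joint, a, b = a, given = character(0)) {
  s <- joint$sigma
  if (!length(given)) return(unname(s[a, b]))
  S_gg <- s[given, given, drop = FALSE]
  unname(s[a, b] - drop(s[a, given, drop = FALSE] %*%
                          solve(S_gg, s[given, b])))
}
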
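#' Linear-Gaussian path models
#'
#' A path model is a directed acyclic graph (DAG) over named variables in
#' which every variable equals an intercept plus a linear combination of its
#' parents plus an independent Gaussian error. It is the scenario definition
#' used throughout the package: the outcome `Y`, exposure `X`, direct
#' predictor `Z`, collider `W`, unmeasured common cause `U`, and the latent
#' normal missingness variable `R` whose thresholding defines the observed
#' missingness indicator.
#'
#' @param variables character vector of variable names (declaration order is
#'   kept for tie-breaking the topological order).
#' @param edges data frame with columns `child`, `parent` and optionally
#'   `coefficient` (default 1), one row per directed edge `parent -> child`.
#' @param error_variances named numeric vector of error variances; variables
#'   not named default to 1. All must be strictly positive.
#' @param means named numeric vector of structural intercepts (default 0).
#'   Marginal means are implied by the structure.
#' @param roles named character vector tagging variables with roles among
#'   `outcome`, `exposure`, `predictor`, `collider`, `unmeasured`,
#'   `missingness`. Exactly one variable must carry the `missingness` role.
#'
#' @return an object of class `path_model` with elements `variables`
#'   (topologically ordered), `B` (square matrix of path coefficients,
#'   `B[child, parent]`), `error_variances`, `means`, `roles`, and `order`
#'   (the topological order used).
#' @seealso [path_model_preset()], [implied_moments()], [simulate_complete()]
#' @export
#' @examples
#' m <- path_model(
#'   variables = c("Y", "X", "Z", "W", "U", "R"),
#'   edges = data.frame(
#'     child  = c("Y", "Y", "W", "W", "R", "R"),
#'     parent = c("X", "Z", "Z", "U", "X", "U")
#'   ),
#'   roles = c(outcome = "Y", exposure = "X", predictor = "Z",
#'             collider = "W", unmeasured = "U", missingness = "R")
#' )
#' implied_moments(m)
path_model <- function(variables, edges = NULL, error_variances = NULL,
                       means = NULL, roles = NULL) {
  if (!is.character(variables) || length(variables) < 1 ||
      anyDuplicated(variables)) {
    stop("`variables` must be distinct variable names")
  }
  k <- length(variables)
  B <- matrix(0, k, k, dimnames = list(variables, variables))
  if (!is.null(edges) && nrow(as.data.frame(edges)) > 0) {
    edges <- as.data.frame(edges)
    if (is.null(edges$coefficient)) edges$coefficient <- 1
    bad <- setdiff(unique(c(edges$child, edges$parent)), variables)
    if (length(bad)) {
      stop("edge references undeclared variable(s): ", paste(bad, collapse = ", "))
    }
    if (any(edges$child == edges$parent)) {
      stop("cycle detected: self-loop on ",
           edges$child[edges$child == edges$parent][1])
    }
    for (i in seq_len(nrow(edges))) {
      B[edges$child[i], edges$parent[i]] <- edges$coefficient[i]
    }
  }
  ev <- rep(1, k); names(ev) <- variables
  if (!is.null(error_variances)) {
    .check_named(error_variances, variables, "error_variances")
    ev[names(error_variances)] <- error_variances
  }
  if (any(!is.finite(ev)) || any(ev <= 0)) {
    stop("all error variances must be strictly positive")
  }
  mu <- rep(0, k); names(mu) <- variables
  if (!is.null(means)) {
    .check_named(means, variables, "means")
    mu[names(means)] <- means
  }
  if (!is.null(roles)) {
    if (is.null(names(roles))) stop("`roles` must be a named vector")
    if (length(bad <- setdiff(unname(roles), variables))) {
      stop("`roles` references undeclared variable(s): ",
           paste(bad, collapse = ", "))
    }
    known <- c("outcome", "exposure", "predictor", "collider",
               "unmeasured", "missingness")
    if (length(setdiff(names(roles), known))) {
      stop("unknown role(s): ",
           paste(setdiff(names(roles), known), collapse = ", "))
    }
    if (sum(names(roles) == "missingness") != 1) {
      stop("exactly one variable must carry the `missingness` role")
    }
  } else {
    stop("`roles` must be supplied (at minimum the `missingness` variable)")
  }
  ord <- .topo_order(B, variables)
  structure(
    list(variables = variables[ord], B = B[ord, ord, drop = FALSE],
         error_variances = ev[ord], means = mu[ord], roles = roles,
         order = variables[ord]),
    class = "path_model"
  )
}

.check_named <- function(x, variables, what) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("`", what, "` must be a named vector")
  }
  bad <- setdiff(names(x), variables)
  if (length(bad)) {
    stop("`", what, "` references undeclared variable(s): ",
         paste(bad, collapse = ", "))
  }
}

# Kahn's algorithm; ties broken by declaration order so the result is
# deterministic for a given specification.
.topo_order <- function(B, variables) {
  k <- length(variables)
  remaining <- seq_len(k)
  ord <- integer(0)
  indeg <- function(i, rem) sum(B[i, rem] != 0)
  while (length(remaining)) {
    src <- remaining[vapply(remaining, indeg, 0, rem = remaining) == 0]
    if (!length(src)) {
      stop("cycle detected among: ",
           paste(variables[remaining], collapse = ", "))
    }
    ord <- c(ord, src[1])
    remaining <- setdiff(remaining, src[1])
  }
  ord
}

#' Built-in scenario presets
#'
#' The four canonical missingness scenarios analysed by the package, each
#' with all path coefficients equal to 1, all error variances equal to 1 and
#' all intercepts 0 unless overridden:
#'
#' * `"fig1"` — partially observed continuous outcome `Y`; edges
#'   `Y <- X`, `Y <- Z`, `W <- Z`, `W <- U`, `R <- X`, `R <- U`. The collider
#'   `W` shares the cause `Z` with `Y` and the cause `U` with `R` (M-bias).
#' * `"fig4"` — partially observed continuous exposure `X`; edges
#'   `Y <- X`, `X <- Z`, `W <- Z`, `W <- U`, `R <- U`. Missingness in `X`
#'   does not depend on `Y`, so complete-records analysis remains valid.
#' * `"fig6"` — as `"fig4"` with the additional edge `R <- Y`: the outcome
#'   also causes missingness in the exposure, invalidating complete-records
#'   analysis.
#' * `"fig8-theoretical"` — the `"fig1"` structure with applied-example
#'   variable names: outcome `bmi7`, exposure `mated`, direct predictor
#'   `pregsize`, collider `bwt`, plus `U` and `R`.
#'
#' @param name preset name.
#' @param coefficients named numeric vector of path-coefficient overrides,
#'   names written `"child~parent"`, e.g. `c("Y~Z" = 0.5)`.
#' @param error_variances,means named overrides passed to [path_model()].
#' @return a [path_model()].
#' @export
#' @examples
#' path_model_preset("fig1", coefficients = c("Y~Z" = 0.5, "W~Z" = 0.5))
path_model_preset <- function(name = c("fig1", "fig4", "fig6", "fig8-theoretical"),
                              coefficients = NULL, error_variances = NULL,
                              means = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    "fig1" = list(
      variables = c("X", "Z", "U", "Y", "W", "R"),
      edges = c("Y~X", "Y~Z", "W~Z", "W~U", "R~X", "R~U"),
      roles = c(outcome = "Y", exposure = "X", predictor = "Z",
                collider = "W", unmeasured = "U", missingness = "R")
    ),
    "fig4" = list(
      variables = c("Z", "U", "X", "Y", "W", "R"),
      edges = c("Y~X", "X~Z", "W~Z", "W~U", "R~U"),
      roles = c(outcome = "Y", exposure = "X", predictor = "Z",
                collider = "W", unmeasured = "U", missingness = "R")
    ),
    "fig6" = list(
      variables = c("Z", "U", "X", "Y", "W", "R"),
      edges = c("Y~X", "X~Z", "W~Z", "W~U", "R~U", "R~Y"),
      roles = c(outcome = "Y", exposure = "X", predictor = "Z",
                collider = "W", unmeasured = "U", missingness = "R")
    ),
    "fig8-theoretical" = list(
      variables = c("mated", "pregsize", "U", "bmi7", "bwt", "R"),
      edges = c("bmi7~mated", "bmi7~pregsize", "bwt~pregsize", "bwt~U",
                "R~mated", "R~U"),
      roles = c(outcome = "bmi7", exposure = "mated", predictor = "pregsize",
                collider = "bwt", unmeasured = "U", missingness = "R")
    )
  )
  ed <- .parse_edge_names(spec$edges)
  ed$coefficient <- 1
  if (!is.null(coefficients)) {
    ov <- .parse_edge_names(names(coefficients))
    for (i in seq_len(nrow(ov))) {
      hit <- ed$child == ov$child[i] & ed$parent == ov$parent[i]
      if (!any(hit)) {
        stop("no such edge in preset '", name, "': ", names(coefficients)[i])
      }
      ed$coefficient[hit] <- coefficients[[i]]
    }
  }
  path_model(spec$variables, ed, error_variances = error_variances,
             means = means, roles = spec$roles)
}

.parse_edge_names <- function(x) {
  parts <- strsplit(x, "~", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("edge names must have the form \"child~parent\"")
  }
  data.frame(child = vapply(parts, `[`, "", 1),
             parent = vapply(parts, `[`, "", 2))
}

#' Read a path model from a YAML or JSON scenario file
#'
#' The file must contain keys `variables`, `edges` (a list of records with
#' `child`, `parent` and optional `coefficient`), and optionally
#' `error_variances`, `means` and `roles` (maps from variable name or role
#' to value).
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return a [path_model()].
#' @export
read_path_model <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  edges <- spec$edges
  if (!is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      data.frame(child = e$child, parent = e$parent,
                 coefficient = if (is.null(e$coefficient)) 1 else e$coefficient)
    }))
  }
  if (!is.null(edges$coefficient)) {
    edges$coefficient[is.na(edges$coefficient)] <- 1
  }
  path_model(
    variables = unlist(spec$variables),
    edges = edges,
    error_variances = unlist(spec$error_variances),
    means = unlist(spec$means),
    roles = unlist(spec$roles)
  )
}

#' @export
print.path_model <- function(x, ...) {
  cat("Linear-Gaussian path model (", length(x$variables), " variables)\n",
      sep = "")
  for (v in x$variables) {
    pa <- names(which(x$B[v, ] != 0))
    rhs <- if (length(pa)) {
      paste(sprintf("%g*%s", x$B[v, pa], pa), collapse = " + ")
    } else "(exogenous)"
    cat(sprintf("  %s = %s + e,  Var(e) = %g\n", v, rhs, x$error_variances[v]))
  }
  cat("  roles:",
      paste(sprintf("%s=%s", names(x$roles), x$roles), collapse = ", "), "\n")
  invisible(x)
}

# Coefficient lookup, zero when the edge is absent.
path_coef <- function(model, child, parent) {
  unname(model$B[child, parent])
}

# Role lookup with a clear error message.
role_var <- function(model, role) {
  v <- model$roles[names(model$roles) == role]
  if (!length(v)) stop("model has no variable with role `", role, "`")
  unname(v[1])
}
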
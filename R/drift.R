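#' Define a drift-rate specification
#'
#' A drift specification names the subset of task regressors (`SR`, `AI`,
#' `DI`, `OR`) whose linear combination forms the drift rate, or declares a
#' constant-only drift. Only the nine admissible specifications (see
#' [drift_specs()]) are accepted.
#'
#' @param regressors Character vector drawn from `c("SR", "AI", "DI", "OR")`,
#'   or `character(0)` with `constant_only = TRUE`.
#' @param constant_only Logical; a constant drift with no regressors.
#' @return An object of class `drift_spec` with elements `regressors`,
#'   `constant_only` and `label`.
#' @examples
#' drift_spec(c("SR", "AI", "DI"))
#' @export
drift_spec <- function(regressors = character(0), constant_only = FALSE) {
  regressors <- toupper(regressors)
  canonical <- c("SR", "AI", "DI", "OR")
  if (!all(regressors %in% canonical)) {
    stop("unknown regressor(s): ",
         paste(setdiff(regressors, canonical), collapse = ", "))
  }
  regressors <- canonical[canonical %in% regressors]
  if (constant_only && length(regressors) > 0) {
    stop("a constant-only drift has no regressors")
  }
  label <- if (constant_only) "constant" else paste(regressors, collapse = "+")
  admissible <- c("SR", "AI", "DI", "SR+AI", "SR+DI", "AI+DI", "SR+OR",
                  "SR+AI+DI", "constant")
  if (!label %in% admissible) {
    stop("'", label, "' is not one of the nine admissible drift ",
         "specifications")
  }
  structure(list(regressors = regressors, constant_only = constant_only,
                 label = label),
            class = "drift_spec")
}

#' Enumerate the nine admissible drift specifications
#'
#' The drift rate is allowed to be any of: a single regressor (`SR`, `AI`,
#' `DI`), the pairs `SR+AI`, `SR+DI`, `AI+DI`, the reward-only pair `SR+OR`,
#' the full inequity model `SR+AI+DI`, or a constant — nine candidate models
#' in a fixed, stable order.
#'
#' @return A named list of nine `drift_spec` objects.
#' @examples
#' names(drift_specs())
#' @export
drift_specs <- function() {
  sets <- list(c("SR"), c("AI"), c("DI"), c("SR", "AI"), c("SR", "DI"),
               c("AI", "DI"), c("SR", "OR"), c("SR", "AI", "DI"))
  specs <- c(lapply(sets, drift_spec),
             list(drift_spec(constant_only = TRUE)))
  names(specs) <- vapply(specs, `[[`, character(1), "label")
  specs
}

#' @export
print.drift_spec <- function(x, ...) {
  cat("Drift specification: delta =",
      if (x$constant_only) "beta0 (constant)"
      else paste(sprintf("beta(%s)*%s", x$regressors, x$regressors),
                 collapse = " + "),
      "\n")
  invisible(x)
}

#' DDM parameter set
#'
#' Bundles the four drift-diffusion parameters: boundary separation `alpha`
#' (> 0, evidence units), relative starting point `z` in (0, 1) measured
#' toward the upper (rejection) boundary, nondecision time `tau` (>= 0,
#' seconds), and the drift coefficients — a named vector `betas` for the
#' spec's regressors, or a scalar `beta0` for a constant-only drift.
#'
#' @param alpha Boundary separation, > 0.
#' @param z Relative starting point in (0, 1); the rejection boundary is the
#'   upper one.
#' @param tau Nondecision time in seconds, >= 0.
#' @param betas Named numeric vector of drift coefficients (names among
#'   `SR`, `AI`, `DI`, `OR`), each inside the prior support (-3, 3).
#' @param beta0 Constant drift (used only by the constant-only spec).
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params(2.16, 0.543, 0.591, betas = c(SR = -0.930, DI = 0.371, AI = 0.254))
#' @export
ddm_params <- function(alpha, z, tau, betas = numeric(0), beta0 = 0) {
  stopifnot(alpha > 0, z > 0, z < 1, tau >= 0)
  if (length(betas) > 0 && is.null(names(betas))) {
    stop("`betas` must be named by regressor")
  }
  if (any(abs(betas) >= 3)) {
    warning("drift coefficient(s) outside the prior support (-3, 3)")
  }
  structure(list(alpha = alpha, z = z, tau = tau,
                 betas = betas, beta0 = beta0),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: alpha = %.3f, z = %.3f, tau = %.3f s\n",
              x$alpha, x$z, x$tau))
  if (length(x$betas) > 0) {
    cat("  drift betas:",
        paste(sprintf("%s = %.3f", names(x$betas), x$betas),
              collapse = ", "), "\n")
  } else {
    cat(sprintf("  constant drift beta0 = %.3f\n", x$beta0))
  }
  invisible(x)
}

#' Drift rate of trials under a specification
#'
#' Evaluates `delta = sum_X beta(X) * X` over the spec's regressors (or
#' `beta0` for a constant-only drift). Positive drift pushes toward the
#' upper, i.e. rejection, boundary.
#'
#' @param spec A [drift_spec()].
#' @param params A [ddm_params()] carrying a coefficient for every regressor
#'   in `spec`.
#' @param features A data.frame from [compute_features()] (columns `sr`,
#'   `or_`, `di`, `ai`).
#' @return Numeric vector of drift rates, one per row of `features`.
#' @examples
#' f <- compute_features(data.frame(sr_yen = 50, or_yen = 450))
#' p <- ddm_params(2.16, 0.543, 0.591,
#'                 betas = c(SR = -0.930, DI = 0.371, AI = 0.254))
#' drift_rate(drift_spec(c("SR", "DI", "AI")), p, f)
#' @export
drift_rate <- function(spec, params, features) {
  stopifnot(inherits(spec, "drift_spec"), inherits(params, "ddm_params"))
  if (spec$constant_only) {
    return(rep(params$beta0, nrow(features)))
  }
  missing <- setdiff(spec$regressors, names(params$betas))
  if (length(missing) > 0) {
    stop("params carry no coefficient for regressor(s): ",
         paste(missing, collapse = ", "))
  }
  X <- feature_matrix(spec, features)
  drop(X %*% params$betas[spec$regressors])
}

# Design matrix of a drift spec (n x k); constant-only is a column of ones.
feature_matrix <- function(spec, features) {
  if (spec$constant_only) {
    return(matrix(1, nrow = nrow(features), ncol = 1,
                  dimnames = list(NULL, "const")))
  }
  cols <- c(SR = "sr", OR = "or_", DI = "di", AI = "ai")[spec$regressors]
  as.matrix(setNames(features[, cols, drop = FALSE], spec$regressors))
}
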
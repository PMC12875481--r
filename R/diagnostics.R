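#' Collinearity diagnostics for the drift regressors
#'
#' Computes the variance inflation factor of each regressor — `1 / (1 - R^2)`
#' from an ordinary-least-squares regression of that regressor on all the
#' others (with intercept) — together with the pairwise Pearson correlation
#' matrix. A VIF above 10 is the conventional collinearity alarm; perfectly
#' collinear designs report `Inf`.
#'
#' @param features A data.frame of regressor columns (e.g. the `di`, `ai`,
#'   `sr` columns of [compute_features()]).
#' @param regressors Character vector of columns to diagnose; defaults to
#'   `c("di", "ai", "sr")`.
#' @return An object of class `ug_design_diagnostics`: a list with `vif`
#'   (named numeric) and `correlation_matrix`.
#' @examples
#' feats <- compute_features(generate_offer_set(seed = 1))
#' design_diagnostics(feats)
#' @export
design_diagnostics <- function(features, regressors = c("di", "ai", "sr")) {
  stopifnot(is.data.frame(features))
  missing <- setdiff(regressors, names(features))
  if (length(missing) > 0) {
    stop("regressor(s) not present: ", paste(missing, collapse = ", "))
  }
  X <- as.data.frame(features[, regressors, drop = FALSE])
  if (nrow(X) < 4) stop("need at least 4 trials for design diagnostics")
  vars <- vapply(X, var, numeric(1))
  if (any(vars == 0)) {
    stop("zero-variance regressor: ",
         paste(regressors[vars == 0], collapse = ", "))
  }
  vif <- vapply(regressors, function(r) {
    fit <- lm(stats::reformulate(setdiff(regressors, r), response = r),
              data = X)
    # a perfectly collinear design is legitimate input here; the usual
    # "perfect fit" warning is the Inf branch below, not a problem
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  structure(
    list(vif = vif, correlation_matrix = cor(X)),
    class = "ug_design_diagnostics"
  )
}

#' @export
print.ug_design_diagnostics <- function(x, ...) {
  cat("Design diagnostics\n  VIF:\n")
  print(round(x$vif, 3))
  cat("  Regressor correlations:\n")
  print(round(x$correlation_matrix, 3))
  invisible(x)
}
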
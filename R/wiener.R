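#' Wiener first-passage-time log density
#'
#' Log density of absorption of a unit-diffusion Wiener process at the named
#' boundary at observed response time `t` (which includes nondecision time
#' `tau`). The upper boundary corresponds to rejection, the lower to
#' acceptance. The density is evaluated by a dual series expansion
#' (small-time image sum vs large-time eigenfunction series), selecting
#' whichever form needs fewer terms at truncation tolerance `eps`. Times at
#' or below `tau` have zero density (`-Inf`).
#'
#' @param t Observed response times in seconds.
#' @param boundary `"upper"` (rejection) or `"lower"` (acceptance); recycled.
#' @param alpha Boundary separation, > 0.
#' @param z Relative starting point in (0, 1) toward the upper boundary.
#' @param tau Nondecision time in seconds.
#' @param drift Drift rate(s); positive values push toward rejection.
#' @param log Return log density (default) or density.
#' @param eps Series truncation tolerance (default `1e-7`).
#' @return Numeric vector of (log) densities.
#' @examples
#' wfpt_density(1.2, "upper", alpha = 2.16, z = 0.543, tau = 0.591,
#'              drift = 1.019)
#' @export
wfpt_density <- function(t, boundary = c("upper", "lower"), alpha, z, tau,
                         drift, log = TRUE, eps = 1e-7) {
  boundary <- match.arg(boundary, several.ok = TRUE)
  stopifnot(is.numeric(t), is.numeric(drift))
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  if (!is.finite(z) || z <= 0 || z >= 1) stop("z must lie in (0, 1)")
  if (!is.finite(tau) || tau < 0) stop("tau must be nonnegative")
  if (any(!is.finite(drift))) stop("drift must be finite")
  n <- max(length(t), length(drift), length(boundary))
  t <- rep_len(t, n)
  drift <- rep_len(drift, n)
  upper <- as.integer(rep_len(boundary, n) == "upper")
  out <- cpp_wfpt_logd(t, upper, alpha, z, tau, drift, eps)
  if (log) out else exp(out)
}

#' Analytic probability of rejection
#'
#' Closed-form probability that the diffusion is absorbed at the upper
#' (rejection) boundary: `P = (1 - exp(-2 v a z)) / (1 - exp(-2 v a))` for
#' drift `v != 0`, and `P = z` at zero drift. Strictly increasing in the
#' drift, with limits 0 and 1.
#'
#' @param alpha Boundary separation, > 0.
#' @param z Relative starting point in (0, 1).
#' @param drift Drift rate(s), positive toward rejection.
#' @return Probability of rejection, in (0, 1).
#' @examples
#' choice_prob(2.16, 0.543, drift = c(-1, 0, 1.019))
#' @export
choice_prob <- function(alpha, z, drift) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  if (!is.finite(z) || z <= 0 || z >= 1) stop("z must lie in (0, 1)")
  if (any(!is.finite(drift))) stop("drift must be finite")
  vapply(drift, function(v) {
    s <- 2 * v * alpha
    if (abs(s) < 1e-9) return(z)
    if (v > 0) {
      expm1(-s * z) / expm1(-s)
    } else {
      # mirror through (v, z) -> (-v, 1 - z) to stay in the stable branch
      1 - expm1(s * (1 - z)) / expm1(s)
    }
  }, numeric(1))
}

#' Analytic mean decision time
#'
#' Unconditional mean first-passage (decision) time of the diffusion between
#' the two boundaries, excluding nondecision time:
#' `E[T] = (alpha * P_reject - z * alpha) / drift` for nonzero drift and
#' `alpha^2 * z * (1 - z)` at zero drift.
#'
#' @inheritParams choice_prob
#' @return Mean decision time(s) in seconds.
#' @examples
#' mean_decision_time(2.16, 0.543, drift = 1.019)
#' @export
mean_decision_time <- function(alpha, z, drift) {
  p <- choice_prob(alpha, z, drift)
  ifelse(abs(drift) < 1e-6,
         alpha^2 * z * (1 - z),
         (alpha * p - z * alpha) / drift)
}

#' Dataset log-likelihood under the DDM
#'
#' Per-trial Wiener first-passage log density at each observed (choice, RT)
#' pair, with rejection on the upper boundary and acceptance on the lower,
#' plus their sum. Timeout trials must be excluded beforehand; any decided
#' trial with `rt_s <= tau` has zero likelihood and is reported by a
#' warning.
#'
#' @param spec A [drift_spec()].
#' @param params A [ddm_params()].
#' @param trials A trial data.frame of decided trials (no timeouts).
#' @param scale_yen Yen per model unit for the regressors (default 100).
#' @param eps Density truncation tolerance.
#' @return List with `total` and `per_trial` log-likelihoods.
#' @export
loglik_trials <- function(spec, params, trials, scale_yen = 100, eps = 1e-7) {
  if (any(trials$choice == "timeout")) {
    stop("timeout trials must be excluded before likelihood evaluation")
  }
  if (nrow(trials) == 0) stop("no trials to evaluate")
  feats <- compute_features(trials, scale_yen)
  v <- drift_rate(spec, params, feats)
  per_trial <- cpp_wfpt_logd(trials$rt_s,
                             as.integer(trials$choice == "reject"),
                             params$alpha, params$z, params$tau, v, eps)
  if (any(trials$rt_s <= params$tau)) {
    warning("trial(s) ", paste(which(trials$rt_s <= params$tau),
                               collapse = ", "),
            " have rt_s <= tau; likelihood is zero")
  }
  list(total = sum(per_trial), per_trial = per_trial)
}
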
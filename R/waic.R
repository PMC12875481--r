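#' Trial-wise widely applicable information criterion
#'
#' Computes, from per-trial posterior log-likelihoods, the log pointwise
#' predictive density `lppd = sum_t log mean_d exp(loglik_td)` (with
#' log-sum-exp stabilization), the variance-form effective-parameter penalty
#' `p_waic = sum_t var_d(loglik_td)`, and the criterion on the deviance
#' scale, `waic = -2 (lppd - p_waic)`. Lower is better.
#'
#' @param x A `ddm_fit` (its stored per-trial log-likelihoods are used), or
#'   a matrix draws x trials, or a 3-d array chains x draws x trials.
#' @return Object of class `waic_result`: list with `waic`, `lppd`,
#'   `p_waic` and `per_trial` (a data.frame of per-trial contributions).
#' @examples
#' ll <- matrix(rnorm(12, -1), nrow = 4) # 4 draws x 3 trials
#' waic(ll)
#' @export
waic <- function(x) {
  ll <- if (inherits(x, "ddm_fit")) x$per_trial_loglik else x
  if (is.array(ll) && length(dim(ll)) == 3) {
    # flatten chains: WAIC is invariant to chain partitioning
    ll <- matrix(ll, nrow = dim(ll)[1] * dim(ll)[2], ncol = dim(ll)[3])
  }
  stopifnot(is.matrix(ll))
  if (ncol(ll) == 0) stop("no trials")
  all_inf <- which(apply(ll, 2, function(v) all(v == -Inf)))
  if (length(all_inf) > 0) {
    stop("WAIC undefined: trial(s) ", paste(all_inf, collapse = ", "),
         " have zero likelihood at every draw")
  }
  nd <- nrow(ll)
  lppd_t <- apply(ll, 2, function(v) {
    mx <- max(v)
    mx + log(mean(exp(v - mx)))
  })
  p_t <- if (nd == 1) rep(0, ncol(ll)) else apply(ll, 2, var)
  structure(
    list(waic = -2 * (sum(lppd_t) - sum(p_t)),
         lppd = sum(lppd_t), p_waic = sum(p_t),
         per_trial = data.frame(lppd = lppd_t, p_waic = p_t,
                                waic = -2 * (lppd_t - p_t)),
         n_trials = ncol(ll), n_draws = nd),
    class = "waic_result"
  )
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC = %.2f (deviance scale; lppd = %.2f, p_waic = %.2f, %d trials)\n",
              x$waic, x$lppd, x$p_waic, x$n_trials))
  invisible(x)
}
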
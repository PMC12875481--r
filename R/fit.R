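#' Prior specification for the DDM parameters
#'
#' The priors used throughout: half-normal(sigma = 2) on boundary separation
#' and nondecision time, uniform(0, 1) on the relative starting point, and
#' uniform(-3, 3) on every drift coefficient.
#'
#' @param alpha_sigma Half-normal scale of the boundary prior (default 2).
#' @param tau_sigma Half-normal scale of the nondecision-time prior
#'   (default 2).
#' @param beta_lower,beta_upper Support of the uniform prior on each drift
#'   coefficient (default -3, 3).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(alpha_sigma = 2, tau_sigma = 2,
                       beta_lower = -3, beta_upper = 3) {
  stopifnot(alpha_sigma > 0, tau_sigma > 0, beta_lower < beta_upper)
  structure(list(alpha_sigma = alpha_sigma, tau_sigma = tau_sigma,
                 beta_lower = beta_lower, beta_upper = beta_upper),
            class = "prior_spec")
}

#' Sample the DDM posterior for one participant
#'
#' Adaptive Metropolis-within-Gibbs sampling of the joint posterior over
#' (alpha, z, tau, betas) under the Wiener first-passage likelihood and the
#' priors of [prior_spec()]. Timeout trials are dropped before fitting.
#' During sampling the nondecision time is additionally restricted to
#' `(0, 0.99 * min(rt))`: the likelihood is identically zero beyond the
#' fastest response, and the restriction keeps chains off that plateau.
#' Proposal scales adapt only during burn-in, so retained draws form a
#' fixed-kernel Markov chain. The per-trial log-likelihood is recorded at
#' every retained draw for trial-wise WAIC.
#'
#' @param trials Trial data.frame of one participant.
#' @param spec A [drift_spec()].
#' @param priors A [prior_spec()].
#' @param chains Number of chains (default 4).
#' @param burn_in Burn-in iterations per chain (default 2000; the full-scale
#'   analysis setting is 15000).
#' @param draws Retained draws per chain (default 2000; full-scale 5000).
#' @param seed Integer seed; the fit is fully reproducible given it.
#' @param scale_yen Yen per model unit (default 100).
#' @param eps Density truncation tolerance.
#' @return An object of class `ddm_fit`: list with `draws` (array chains x
#'   draws x parameters), `parameters`, `per_trial_loglik` (chains x draws x
#'   trials), `accept` rates, `spec`, `trials` (the fitted subset), `seed`
#'   and sampler settings.
#' @export
fit_ddm <- function(trials, spec, priors = prior_spec(), chains = 4,
                    burn_in = 2000, draws = 2000, seed = 1,
                    scale_yen = 100, eps = 1e-7) {
  stopifnot(inherits(spec, "drift_spec"), inherits(priors, "prior_spec"),
            chains >= 1, burn_in >= 0, draws >= 1)
  trials <- validate_trials(trials)
  fitted <- valid_trials(trials)
  if (nrow(fitted) == 0) {
    stop("no decided trials to fit (all trials are timeouts or the table ",
         "is empty)")
  }
  feats <- compute_features(fitted, scale_yen)
  X <- feature_matrix(spec, feats)
  tau_max <- 0.99 * min(fitted$rt_s)
  res <- withr::with_seed(as.integer(seed), {
    cpp_sample_ddm(X, fitted$rt_s, as.integer(fitted$choice == "reject"),
                   as.integer(chains), as.integer(burn_in),
                   as.integer(draws), priors$alpha_sigma, priors$tau_sigma,
                   priors$beta_lower, priors$beta_upper, tau_max, eps)
  })
  pars <- c("alpha", "z", "tau",
            if (spec$constant_only) "beta0"
            else paste0("beta_", spec$regressors))
  dimnames(res$draws) <- list(NULL, NULL, pars)
  structure(
    list(draws = res$draws, parameters = pars,
         per_trial_loglik = res$loglik, accept = res$accept,
         reinitializations = res$reinit, spec = spec, priors = priors,
         trials = fitted, n_trials = nrow(fitted),
         n_timeouts = sum(trials$choice == "timeout"),
         chains = chains, burn_in = burn_in, n_draws = draws,
         tau_max = tau_max, scale_yen = scale_yen, seed = seed),
    class = "ddm_fit"
  )
}

#' Posterior means of a DDM fit
#'
#' The package's point-estimate convention: the posterior mean of every
#' parameter, pooled over chains.
#'
#' @param fit A `ddm_fit`.
#' @return Named numeric vector of posterior means.
#' @export
posterior_means <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  apply(fit$draws, 3, mean)
}

#' Posterior means as a `ddm_params` object
#'
#' @param fit A `ddm_fit`.
#' @return A [ddm_params()] at the posterior means.
#' @export
posterior_params <- function(fit) {
  m <- posterior_means(fit)
  if (fit$spec$constant_only) {
    ddm_params(m["alpha"], m["z"], m["tau"], beta0 = unname(m["beta0"]))
  } else {
    betas <- m[paste0("beta_", fit$spec$regressors)]
    names(betas) <- fit$spec$regressors
    ddm_params(m["alpha"], m["z"], m["tau"], betas = betas)
  }
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("DDM fit (%s drift): %d trials, %d chains x %d draws\n",
              x$spec$label, x$n_trials, x$chains, x$n_draws))
  m <- posterior_means(x)
  s <- apply(x$draws, 3, sd)
  tab <- data.frame(mean = round(m, 3), sd = round(s, 3))
  print(tab)
  invisible(x)
}
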
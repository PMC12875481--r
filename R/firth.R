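#' Bias-reduced (Firth) logistic value model of choice
#'
#' The value-based alternative to the DDM: the rejection probability is
#' `p_reject(t) = 1 / (1 + exp(-v(t)))` with value difference
#' `v(t) = V_reject - V_accept = gamma0 * (g_reject - g_accept)
#' + gamma_AI * AI + gamma_DI * DI`, where the gain of rejecting is 0 and the
#' gain of accepting is the (scaled) self-reward. The coefficients are
#' estimated by maximizing the Firth-penalized likelihood (Jeffreys-prior
#' penalty), which keeps every estimate finite even under complete
#' separation — e.g. a participant who accepted every offer.
#'
#' @param trials Trial data.frame of one participant (timeouts are dropped).
#' @param scale_yen Yen per model unit (default 100).
#' @return Object of class `value_fit`: list with `gamma` (named vector
#'   `gamma0`, `gamma_AI`, `gamma_DI`), `fitted_p_reject`, `v`,
#'   `converged`, `n_trials`.
#' @examples
#' offers <- generate_offer_set(seed = 2)
#' p <- ddm_params(2.2, 0.5, 0.5, betas = c(SR = -0.9, DI = 1, AI = 0.3))
#' sim <- simulate_dataset(drift_spec(c("SR", "DI", "AI")), p, offers, seed = 3)
#' fit_value_logistic(sim)
#' @export
fit_value_logistic <- function(trials, scale_yen = 100) {
  trials <- valid_trials(validate_trials(trials))
  if (nrow(trials) < 3) stop("insufficient data: need at least 3 trials")
  if (!any(trials$choice == "accept")) {
    stop("need at least one accepted trial")
  }
  feats <- compute_features(trials, scale_yen)
  X <- value_design(feats)
  y <- as.numeric(trials$choice == "reject")
  res <- firth_logistic(X, y)
  gamma <- setNames(res$beta, c("gamma0", "gamma_AI", "gamma_DI"))
  eta <- drop(X %*% res$beta)
  structure(list(gamma = gamma, v = eta, fitted_p_reject = plogis(eta),
                 converged = res$converged, loglik = res$loglik,
                 penalized_loglik = res$penalized_loglik,
                 n_trials = nrow(trials)),
            class = "value_fit")
}

# Value-model design matrix: columns (g_reject - g_accept, AI, DI) = (-SR,
# AI, DI); no intercept.
value_design <- function(feats) {
  cbind(gain_diff = -feats$sr, AI = feats$ai, DI = feats$di)
}

# Firth-penalized logistic regression by Newton scoring with the
# hat-value-adjusted score, with step-halving on the penalized likelihood.
firth_logistic <- function(X, y, max_iter = 200, tol = 1e-10) {
  penll <- function(beta) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    W <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(X * sqrt(W))
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus
  }
  beta <- rep(0, ncol(X))
  ll <- penll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    W <- pmax(p * (1 - p), 1e-12)
    XW <- X * sqrt(W)
    info <- crossprod(XW)
    h <- rowSums((XW %*% solve(info)) * XW) # leverages of the weighted fit
    score <- drop(t(X) %*% (y - p + h * (0.5 - p)))
    step <- solve(info, score)
    # step-halving: never decrease the penalized likelihood
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- penll(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    beta_new <- beta + lambda * step
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    ll <- penll(beta)
    if (moved < tol || max(abs(score)) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  list(beta = beta, converged = converged,
       loglik = sum(y * eta - log1p(exp(eta))),
       penalized_loglik = penll(beta))
}

#' @export
print.value_fit <- function(x, ...) {
  cat("Bias-reduced logistic value model\n")
  print(round(x$gamma, 4))
  cat(sprintf("  %d trials, penalized loglik %.3f%s\n", x$n_trials,
              x$penalized_loglik,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
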
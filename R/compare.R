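#' Choice-only comparison of the DDM and the logistic value model
#'
#' Strips response times out of the comparison: both model families are
#' scored on the Bernoulli likelihood of accept/reject alone, via WAIC. For
#' the DDM, each posterior draw's analytic rejection probability per trial
#' feeds the Bernoulli log-likelihood; for the value model, a Bayesian
#' logistic posterior under wide normal(0, 10^2) coefficient priors is
#' sampled and scored the same way. Per-participant coefficient tables
#' (posterior-mean DDM betas, Firth gamma estimates) are reported alongside.
#'
#' @param trials Multi-participant trial data.frame.
#' @param spec Drift specification of the DDM (default the full `SR+AI+DI`
#'   model).
#' @param fits Optional named list of prefitted `ddm_fit` objects (names =
#'   participant ids, fitted on the same trials); fitted internally when
#'   omitted.
#' @param priors,chains,burn_in,draws,seed,scale_yen Sampler settings used
#'   for any internal fits and for the logistic posterior.
#' @return Object of class `choice_comparison`: list with `by_participant`
#'   (data.frame), `total_waic_ddm`, `total_waic_logistic`.
#' @export
compare_choice_only <- function(trials, spec = drift_spec(c("SR", "AI", "DI")),
                                fits = NULL, priors = prior_spec(),
                                chains = 4, burn_in = 1000, draws = 1000,
                                seed = 1, scale_yen = 100) {
  trials <- validate_trials(trials)
  ids <- unique(trials$participant_id)
  rows <- lapply(seq_along(ids), function(i) {
    tr <- valid_trials(trials[trials$participant_id == ids[i], ])
    fit <- if (is.null(fits)) {
      fit_ddm(tr, spec, priors, chains = chains, burn_in = burn_in,
              draws = draws, seed = derive_seed(seed, i),
              scale_yen = scale_yen)
    } else {
      f <- fits[[ids[i]]]
      if (is.null(f)) stop("no prefitted DDM for participant ", ids[i])
      if (f$n_trials != nrow(tr)) {
        stop("trial-set mismatch for participant ", ids[i],
             ": DDM fitted on ", f$n_trials, " trials, table has ", nrow(tr))
      }
      f
    }
    feats <- compute_features(tr, scale_yen)
    y <- as.numeric(tr$choice == "reject")

    # DDM choice-only WAIC from analytic rejection probabilities per draw
    nd <- dim(fit$draws)[1] * dim(fit$draws)[2]
    th <- matrix(fit$draws, nrow = nd, ncol = dim(fit$draws)[3])
    colnames(th) <- fit$parameters
    V <- if (spec$constant_only) {
      matrix(th[, "beta0"], nrow = nd, ncol = nrow(tr))
    } else {
      th[, paste0("beta_", spec$regressors), drop = FALSE] %*%
        t(feature_matrix(spec, feats))
    }
    P <- choice_prob_mat(th[, "alpha"], th[, "z"], V)
    ll_ddm <- sweep(log(P), 2, y, `*`) + sweep(log1p(-P), 2, 1 - y, `*`)
    w_ddm <- waic(ll_ddm)

    # Bayesian logistic WAIC under normal(0, 100) priors
    Xv <- value_design(feats)
    lg <- logistic_posterior(Xv, y, chains = chains, burn_in = burn_in,
                             draws = draws, seed = derive_seed(seed, 1e6 + i))
    ll_lg <- bernoulli_loglik_mat(lg$draws, Xv, y)
    w_lg <- waic(ll_lg)

    firth <- tryCatch(fit_value_logistic(tr, scale_yen), error = function(e) NULL)
    pm <- posterior_means(fit)
    out <- data.frame(participant_id = ids[i],
                      waic_ddm_choice = w_ddm$waic,
                      waic_logistic = w_lg$waic,
                      stringsAsFactors = FALSE)
    for (p in fit$parameters) out[[p]] <- unname(pm[p])
    out$gamma0 <- if (is.null(firth)) NA else unname(firth$gamma["gamma0"])
    out$gamma_AI <- if (is.null(firth)) NA else unname(firth$gamma["gamma_AI"])
    out$gamma_DI <- if (is.null(firth)) NA else unname(firth$gamma["gamma_DI"])
    out
  })
  by_participant <- do.call(rbind, rows)
  structure(list(by_participant = by_participant,
                 total_waic_ddm = sum(by_participant$waic_ddm_choice),
                 total_waic_logistic = sum(by_participant$waic_logistic),
                 spec = spec$label, seed = seed),
            class = "choice_comparison")
}

# Vectorized rejection probability for matrices of draws: alpha, z are
# per-draw vectors, V is a draws x trials drift matrix.
choice_prob_mat <- function(alpha, z, V) {
  S <- -2 * alpha * V # note: row-wise recycling over columns
  Z <- matrix(z, nrow = nrow(V), ncol = ncol(V))
  P <- ifelse(abs(S) < 1e-9, Z,
              ifelse(S < 0, expm1(S * Z) / expm1(S),
                     1 - expm1(-S * (1 - Z)) / expm1(-S)))
  pmin(pmax(P, 1e-12), 1 - 1e-12)
}

# Per-draw Bernoulli log-likelihood matrix (draws x trials).
bernoulli_loglik_mat <- function(B, X, y) {
  eta <- B %*% t(X)
  P <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  sweep(log(P), 2, y, `*`) + sweep(log1p(-P), 2, 1 - y, `*`)
}

# Adaptive random-walk Metropolis for the Bayesian logistic model with
# normal(0, sd = 10) coefficient priors. Returns pooled draws.
logistic_posterior <- function(X, y, chains = 4, burn_in = 1000,
                               draws = 1000, seed = 1, prior_sd = 10) {
  k <- ncol(X)
  withr::with_seed(as.integer(seed), {
    out <- matrix(NA_real_, nrow = chains * draws, ncol = k)
    logpost <- function(b) {
      eta <- drop(X %*% b)
      sum(y * eta - log1p(exp(eta))) - sum(b^2) / (2 * prior_sd^2)
    }
    for (c in seq_len(chains)) {
      b <- rnorm(k, 0, 0.5)
      lp <- logpost(b)
      lsd <- rep(log(0.5), k)
      for (it in seq_len(burn_in + draws)) {
        for (j in seq_len(k)) {
          prop <- b
          prop[j] <- b[j] + exp(lsd[j]) * rnorm(1)
          lp_new <- logpost(prop)
          acc <- is.finite(lp_new) && log(runif(1)) < lp_new - lp
          if (acc) {
            b <- prop
            lp <- lp_new
          }
          if (it <= burn_in) {
            lsd[j] <- lsd[j] + min(0.25, 3 / sqrt(it)) *
              ((if (acc) 1 else 0) - 0.44)
          }
        }
        if (it > burn_in) out[(c - 1) * draws + it - burn_in, ] <- b
      }
    }
    list(draws = out)
  })
}

#' @export
print.choice_comparison <- function(x, ...) {
  cat(sprintf(
    "Choice-only WAIC: DDM (%s drift) = %.1f, logistic value model = %.1f\n",
    x$spec, x$total_waic_ddm, x$total_waic_logistic))
  cat(sprintf("  %d participants\n", nrow(x$by_participant)))
  invisible(x)
}
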
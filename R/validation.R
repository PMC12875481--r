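#' Ground-truth agent specifications
#'
#' Canonical simulated agents for recovery experiments under the full
#' `SR+AI+DI` drift: a *reward seeker*, driven only by self-reward
#' (`beta(SR) < 0`, inequity coefficients zero), and an *inequity avoider*
#' with a positive disadvantageous-inequity coefficient.
#'
#' @param label One of `"reward_seeker"`, `"inequity_avoider"`, `"custom"`.
#' @param params A [ddm_params()]; required for `"custom"`, defaults
#'   otherwise to (alpha 2, z 0.5, tau 0.5 s) with betas
#'   `SR = -1.5, DI = 0, AI = 0` (reward seeker) or
#'   `SR = -0.5, DI = 1, AI = 0.5` (inequity avoider).
#' @param spec Drift specification (default `SR+AI+DI`).
#' @return Object of class `agent_spec`.
#' @export
agent_spec <- function(label = c("reward_seeker", "inequity_avoider",
                                 "custom"),
                       params = NULL,
                       spec = drift_spec(c("SR", "AI", "DI"))) {
  label <- match.arg(label)
  if (is.null(params)) {
    params <- switch(label,
      reward_seeker = ddm_params(2, 0.5, 0.5,
                                 betas = c(SR = -1.5, AI = 0, DI = 0)),
      inequity_avoider = ddm_params(2, 0.5, 0.5,
                                    betas = c(SR = -0.5, AI = 0.5, DI = 1)),
      custom = stop("a custom agent needs explicit `params`")
    )
  }
  stopifnot(inherits(params, "ddm_params"), inherits(spec, "drift_spec"))
  if (label == "reward_seeker" &&
      (params$betas["SR"] >= 0 || any(params$betas[c("AI", "DI")] != 0))) {
    stop("a reward seeker has beta(SR) < 0 and beta(DI) = beta(AI) = 0")
  }
  if (label == "inequity_avoider" && params$betas["DI"] <= 0) {
    stop("an inequity avoider has beta(DI) > 0")
  }
  structure(list(label = label, params = params, spec = spec),
            class = "agent_spec")
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a full task run (fresh jittered offer set, simulated
#' choices and response times) from a known agent, refits the posterior on
#' each simulated dataset, and summarizes how well the posterior means
#' recover the ground truth (bias and RMSE per parameter). Repeats whose fit
#' fails (e.g. an all-timeout simulation) are excluded and counted.
#'
#' @param agent An [agent_spec()].
#' @param n_trials Trials per simulated run; the task design uses 56.
#' @param n_repeats Number of simulate-and-refit repeats (default 20; the
#'   full-scale experiment uses 100).
#' @param chains,burn_in,draws,priors Sampler settings per refit.
#' @param seed Master seed.
#' @param scale_yen Yen per model unit.
#' @return Object of class `recovery_result`: `truth`, `estimates`
#'   (n_repeats x parameters), `bias`, `rmse`, `n_failed`.
#' @export
parameter_recovery <- function(agent, n_trials = 56, n_repeats = 20,
                               chains = 4, burn_in = 1000, draws = 1000,
                               priors = prior_spec(), seed = 1,
                               scale_yen = 100) {
  stopifnot(inherits(agent, "agent_spec"))
  if (n_repeats < 1) stop("`n_repeats` must be at least 1")
  if (n_trials %% 7 != 0) {
    stop("`n_trials` must be a multiple of the 7 task conditions")
  }
  spec <- agent$spec
  truth <- c(alpha = agent$params$alpha, z = agent$params$z,
             tau = agent$params$tau)
  if (spec$constant_only) {
    truth <- c(truth, beta0 = agent$params$beta0)
  } else {
    b <- agent$params$betas[spec$regressors]
    names(b) <- paste0("beta_", spec$regressors)
    truth <- c(truth, b)
  }
  est <- matrix(NA_real_, nrow = n_repeats, ncol = length(truth),
                dimnames = list(NULL, names(truth)))
  failed <- logical(n_repeats)
  for (r in seq_len(n_repeats)) {
    offers <- generate_offer_set(derive_seed(seed, 2 * r),
                                 trials_per_condition = n_trials / 7)
    sim <- simulate_dataset(spec, agent$params, offers,
                            seed = derive_seed(seed, 2 * r + 1),
                            scale_yen = scale_yen)
    res <- tryCatch(
      fit_ddm(sim, spec, priors, chains = chains, burn_in = burn_in,
              draws = draws, seed = derive_seed(seed, 10000 + r),
              scale_yen = scale_yen),
      error = function(e) NULL
    )
    if (is.null(res)) {
      failed[r] <- TRUE
    } else {
      est[r, ] <- posterior_means(res)[colnames(est)]
    }
  }
  ok <- est[!failed, , drop = FALSE]
  structure(
    list(agent = agent$label, truth = truth, estimates = est,
         bias = colMeans(ok) - truth,
         rmse = sqrt(colMeans((ok - rep(truth, each = nrow(ok)))^2)),
         n_repeats = n_repeats, n_failed = sum(failed), seed = seed),
    class = "recovery_result"
  )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("Parameter recovery (%s agent, %d repeats, %d failed)\n",
              x$agent, x$n_repeats, x$n_failed))
  print(round(rbind(truth = x$truth, bias = x$bias, rmse = x$rmse), 3))
  invisible(x)
}

#' Leave-one-out response-time cross-validation
#'
#' The generalization check of the fitted DDM for a single participant: in
#' each of 8 folds one trial per condition is held out, the model is refitted
#' on the remaining trials, and the held-out response time is predicted as
#' the posterior-mean nondecision time plus the analytic mean decision time
#' at the held-out offer's drift. Reports predicted-vs-actual pairs per
#' condition with Pearson correlations, Holm-adjusted over the 7 conditions.
#'
#' @param trials Trial data.frame of one participant (ideally 8 decided
#'   trials per condition; fewer triggers a warning and fold recycling).
#' @param spec Drift specification (default `SR+AI+DI`).
#' @param chains,burn_in,draws,priors Sampler settings per fold.
#' @param seed Master seed.
#' @param scale_yen Yen per model unit.
#' @param folds Number of folds (default 8, one per within-condition trial).
#' @return Object of class `cv_report`: `pairs` (data.frame fold x condition
#'   with predicted/actual RT), `by_condition` (r, p, Holm-adjusted p per
#'   condition), `folds`.
#' @export
loo_cv_rt <- function(trials, spec = drift_spec(c("SR", "AI", "DI")),
                      chains = 4, burn_in = 1000, draws = 1000,
                      priors = prior_spec(), seed = 1, scale_yen = 100,
                      folds = 8) {
  trials <- valid_trials(validate_trials(trials))
  if (length(unique(trials$participant_id)) != 1) {
    stop("cross-validation runs on a single participant's trials")
  }
  conds <- base_offers()$condition_label
  n_cond <- table(factor(trials$condition_label, levels = conds))
  if (any(n_cond < 2)) {
    stop("cannot build folds: condition(s) ",
         paste(conds[n_cond < 2], collapse = ", "), " have fewer than 2 trials")
  }
  if (any(n_cond < folds)) {
    warning("condition(s) with fewer than ", folds,
            " trials; held-out trials recycle within condition")
  }
  pairs <- NULL
  for (f in seq_len(folds)) {
    hold_idx <- unlist(lapply(conds, function(cl) {
      ids <- which(trials$condition_label == cl)
      ids[(f - 1) %% length(ids) + 1]
    }))
    train <- trials[-hold_idx, ]
    test <- trials[hold_idx, ]
    fit <- fit_ddm(train, spec, priors, chains = chains, burn_in = burn_in,
                   draws = draws, seed = derive_seed(seed, f),
                   scale_yen = scale_yen)
    pm <- posterior_params(fit)
    v <- drift_rate(spec, pm, compute_features(test, scale_yen))
    pred <- pm$tau + mean_decision_time(pm$alpha, pm$z, v)
    pairs <- rbind(pairs, data.frame(
      fold = f, condition_label = test$condition_label,
      predicted_rt = pred, actual_rt = test$rt_s))
  }
  by_condition <- do.call(rbind, lapply(conds, function(cl) {
    p <- pairs[pairs$condition_label == cl, ]
    if (sd(p$actual_rt) == 0 || sd(p$predicted_rt) == 0) {
      return(data.frame(condition_label = cl, n = nrow(p), r = NA_real_,
                        p_value = NA_real_))
    }
    ct <- cor.test(p$predicted_rt, p$actual_rt)
    data.frame(condition_label = cl, n = nrow(p),
               r = unname(ct$estimate), p_value = ct$p.value)
  }))
  by_condition$p_holm <- NA_real_
  defined <- !is.na(by_condition$p_value)
  by_condition$p_holm[defined] <- p.adjust(by_condition$p_value[defined],
                                           method = "holm")
  structure(list(pairs = pairs, by_condition = by_condition, folds = folds,
                 spec = spec$label, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Leave-one-out RT cross-validation (%s drift, %d folds)\n",
              x$spec, x$folds))
  print(transform(x$by_condition, r = round(r, 3),
                  p_value = signif(p_value, 3), p_holm = signif(p_holm, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Posterior-predictive simulation of cohort behavior
#'
#' Simulates behavior from each participant's fitted (posterior-mean)
#' parameters over a common offer set and aggregates it into the same shape
#' as the observed-behavior tables: per-condition predictive rejection rates
#' and mean response times by choice.
#'
#' @param fits A named list of `ddm_fit` objects (names = participant ids)
#'   or a data.frame of posterior-mean parameters with a `participant_id`
#'   column and columns `alpha`, `z`, `tau`, `beta_*`.
#' @param offers Offer data.frame used for every simulated run.
#' @param n_sims Simulated datasets per participant (default 10).
#' @param seed Master seed.
#' @param spec Drift specification (default `SR+AI+DI`); ignored for
#'   `ddm_fit` input, which carries its own.
#' @param scale_yen Yen per model unit.
#' @return Object of class `predictive_summary`: `by_condition` (rejection
#'   rate and accept/reject mean RTs per condition) and the simulated
#'   `trials`.
#' @export
posterior_predictive <- function(fits, offers, n_sims = 10, seed = 1,
                                 spec = drift_spec(c("SR", "AI", "DI")),
                                 scale_yen = 100) {
  if (is.data.frame(fits)) {
    ids <- fits$participant_id
    get_params <- function(i) {
      row <- fits[i, ]
      bn <- grep("^beta_", names(fits), value = TRUE)
      betas <- as.numeric(row[bn])
      names(betas) <- sub("^beta_", "", bn)
      list(params = ddm_params(row$alpha, row$z, row$tau, betas = betas),
           spec = spec)
    }
  } else {
    ids <- names(fits)
    if (is.null(ids)) stop("`fits` must be named by participant id")
    get_params <- function(i) list(params = posterior_params(fits[[i]]),
                                   spec = fits[[i]]$spec)
  }
  sims <- list()
  for (i in seq_along(ids)) {
    gp <- get_params(i)
    for (s in seq_len(n_sims)) {
      sims[[length(sims) + 1]] <- simulate_dataset(
        gp$spec, gp$params, offers,
        seed = derive_seed(seed, i * 1000 + s),
        participant_id = paste0(ids[i], "_sim", s), scale_yen = scale_yen)
    }
  }
  trials <- do.call(rbind, sims)
  by_condition <- condition_table(trials)
  structure(list(by_condition = by_condition, trials = trials,
                 n_sims = n_sims, seed = seed),
            class = "predictive_summary")
}

#' @export
print.predictive_summary <- function(x, ...) {
  cat("Posterior-predictive behavior (", x$n_sims,
      " simulations/participant)\n", sep = "")
  print(transform(x$by_condition, rejection_rate = round(rejection_rate, 3),
                  mean_rt_accept = round(mean_rt_accept, 3),
                  mean_rt_reject = round(mean_rt_reject, 3)),
        row.names = FALSE)
  invisible(x)
}
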
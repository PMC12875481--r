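test_that("exactly the nine admissible drift specifications are enumerated", {
  specs <- drift_specs()
  expect_length(specs, 9)
  expect_true("SR+OR" %in% names(specs))
  expect_true("constant" %in% names(specs))
  expect_true("SR+AI+DI" %in% names(specs))
  expect_identical(names(specs),
                   c("SR", "AI", "DI", "SR+AI", "SR+DI", "AI+DI", "SR+OR",
                     "SR+AI+DI", "constant"))
  expect_error(drift_spec(c("DI", "OR")), "not one of the nine")
  expect_error(drift_spec("XX"), "unknown regressor")
  expect_error(drift_spec("SR", constant_only = TRUE), "no regressors")
})

test_that("a single-participant single-spec selection yields a one-row table", {
  sim <- simulate_dataset(spec_full(), anchor_params(),
                          generate_offer_set(seed = 31), seed = 32)
  sel <- run_selection(sim, specs = drift_specs()["SR+DI"], chains = 2,
                       burn_in = 200, draws = 200, seed = 33)
  expect_equal(nrow(sel$table), 1)
  expect_equal(sel$best_spec, "SR+DI")
  expect_equal(dim(sel$per_participant), c(1, 1))
  expect_equal(sel$table$n_failed, 0)
})

test_that("the Firth fit stays finite under complete separation", {
  # reject exactly when DI > 0: perfectly separated
  tr <- make_trials(rep(c("1/9", "1/4", "7/3", "3/2"), each = 2),
                    rep(c("reject", "reject", "accept", "accept"), each = 2),
                    rep(1.5, 8))
  fit <- fit_value_logistic(tr)
  expect_true(all(is.finite(fit$gamma)))
  expect_gt(fit$gamma[["gamma_DI"]], 0)

  # all-accept participant: finite, shrunk coefficients
  tr2 <- make_trials(rep(base_offers()$condition_label, 2),
                     rep("accept", 14), rep(2, 14))
  fit2 <- fit_value_logistic(tr2)
  expect_true(all(is.finite(fit2$gamma)))
  expect_true(all(abs(fit2$gamma) < 5))
  expect_true(all(fit2$fitted_p_reject < 0.5))

  expect_error(fit_value_logistic(make_trials("1/9", "accept", 1)),
               "at least 3")
})

test_that("Firth estimates match an independent penalized-likelihood optimum", {
  sim <- simulate_dataset(spec_full(),
                          ddm_params(2, 0.5, 0.5,
                                     betas = c(SR = -0.8, DI = 1.2, AI = 0.4)),
                          generate_offer_set(seed = 41), seed = 42)
  sim <- sim[sim$choice != "timeout", ][1:20, ]
  fit <- fit_value_logistic(sim)

  feats <- compute_features(sim)
  X <- cbind(-feats$sr, feats$ai, feats$di)
  y <- as.numeric(sim$choice == "reject")
  penll <- function(b) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    info <- crossprod(X * sqrt(pmax(p * (1 - p), 1e-12)))
    -(sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus)
  }
  opt <- optim(c(0, 0, 0), penll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  opt <- optim(opt$par, penll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(unname(fit$gamma), opt$par, tolerance = 1e-3)
})

test_that("bias reduction shrinks small-sample coefficient bias relative to ML", {
  set.seed(7)
  truth <- c(1, 0.8) # intercept-free 2-column design
  n <- 20
  reps <- 150
  est_firth <- est_ml <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    X <- cbind(rnorm(n), rnorm(n))
    p <- plogis(drop(X %*% truth))
    y <- rbinom(n, 1, p)
    est_firth[r, ] <- ugddm:::firth_logistic(X, y)$beta
    ml <- suppressWarnings(glm.fit(X, y, family = binomial()))
    est_ml[r, ] <- pmin(pmax(ml$coefficients, -50), 50)
  }
  bias_firth <- abs(colMeans(est_firth) - truth)
  bias_ml <- abs(colMeans(est_ml) - truth)
  expect_true(all(bias_firth < bias_ml))
})

test_that("choice-only comparison is deterministic with one row per participant", {
  p1 <- ddm_params(2, 0.5, 0.4, betas = c(SR = -0.6, DI = 1, AI = 0.3))
  p2 <- ddm_params(2.4, 0.55, 0.5, betas = c(SR = -1.2, DI = 0.3, AI = 0))
  trials <- rbind(
    simulate_dataset(spec_full(), p1, generate_offer_set(seed = 51),
                     seed = 52, participant_id = "A"),
    simulate_dataset(spec_full(), p2, generate_offer_set(seed = 53),
                     seed = 54, participant_id = "B"))
  cmp1 <- compare_choice_only(trials, chains = 2, burn_in = 300, draws = 300,
                              seed = 61)
  cmp2 <- compare_choice_only(trials, chains = 2, burn_in = 300, draws = 300,
                              seed = 61)
  expect_identical(cmp1$by_participant, cmp2$by_participant)
  expect_equal(nrow(cmp1$by_participant), 2)
  expect_setequal(cmp1$by_participant$participant_id, c("A", "B"))
  expect_true(all(c("beta_DI", "gamma_DI") %in% names(cmp1$by_participant)))
  expect_error(
    compare_choice_only(trials, fits = list(A = quick_fit(
      trials[trials$participant_id == "A", ][1:10, ]))),
    "mismatch|no prefitted")
})

test_that("with pure-noise response times the logistic choice fit is not worse", {
  # choices generated from a logistic value rule; RTs carry no signal
  withr::with_seed(71, {
    offers <- generate_offer_set(seed = 72)
    feats <- compute_features(offers)
    v <- -1.2 * feats$sr + 0.5 * feats$ai + 1.5 * feats$di
    trials <- data.frame(
      participant_id = "N1", trial_index = seq_len(56) - 1L,
      condition_label = offers$condition_label,
      sr_yen = offers$sr_yen, or_yen = offers$or_yen,
      choice = ifelse(runif(56) < plogis(v), "reject", "accept"),
      rt_s = round(runif(56, 0.4, 9.5), 3), stringsAsFactors = FALSE)
  })
  cmp <- compare_choice_only(trials, chains = 2, burn_in = 400, draws = 400,
                             seed = 73)
  expect_lte(cmp$total_waic_logistic, cmp$total_waic_ddm)
})
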
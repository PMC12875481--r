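test_that("drift rate is the stated linear combination of features", {
  f <- compute_features(data.frame(sr_yen = 50, or_yen = 450))
  p <- anchor_params()
  expect_equal(drift_rate(spec_full(), p, f),
               -0.930 * 0.5 + 0.371 * 4.0 + 0.254 * 0)
  expect_equal(drift_rate(spec_full(), p, f), 1.019)

  p0 <- ddm_params(2, 0.5, 0.5, betas = c(SR = 0, DI = 0, AI = 0))
  expect_equal(drift_rate(spec_full(), p0, f), 0)

  p2 <- ddm_params(2.16, 0.543, 0.591,
                   betas = c(SR = -1.86, DI = 0.742, AI = 0.508))
  expect_equal(drift_rate(spec_full(), p2, f),
               2 * drift_rate(spec_full(), anchor_params(), f))

  p_miss <- ddm_params(2, 0.5, 0.5, betas = c(SR = -1))
  expect_error(drift_rate(spec_full(), p_miss, f), "no coefficient")
})

test_that("choice probability has the right fixed points, monotonicity and limits", {
  expect_equal(choice_prob(2, 0.5, 0), 0.5)
  expect_equal(choice_prob(2, 0.3, 0), 0.3)
  v <- seq(-6, 6, by = 0.25)
  p <- choice_prob(2.16, 0.543, v)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  expect_gt(choice_prob(2, 0.5, 15), 1 - 1e-10)
  expect_lt(choice_prob(2, 0.5, -15), 1e-10)
  expect_error(choice_prob(2, 0.5, Inf), "finite")
})

test_that("FPT density is symmetric at zero drift and zero at the support edge", {
  tt <- seq(0.7, 5, by = 0.3)
  up <- wfpt_density(tt, "upper", 2, 0.5, 0.6, 0, log = FALSE)
  lo <- wfpt_density(tt, "lower", 2, 0.5, 0.6, 0, log = FALSE)
  expect_equal(up, lo)
  expect_identical(wfpt_density(0.6, "upper", 2, 0.5, 0.6, 1), -Inf)
  expect_identical(wfpt_density(0.1, "lower", 2, 0.5, 0.6, 1), -Inf)
  expect_error(wfpt_density(1, "upper", -1, 0.5, 0, 0), "alpha")
  expect_error(wfpt_density(1, "upper", 2, 1.2, 0, 0), "z")
})

test_that("series density matches an independent image-sum implementation", {
  grid <- expand.grid(t = c(0.8, 1.5, 3.0), alpha = c(0.8, 2.16),
                      z = c(0.3, 0.543), drift = c(-1.5, 0.4),
                      boundary = c("upper", "lower"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- wfpt_density(g$t, g$boundary, g$alpha, g$z, 0.5, g$drift,
                        log = FALSE)
    want <- wfpt_density_oracle(g$t, g$boundary, g$alpha, g$z, 0.5, g$drift)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("dataset log-likelihood is a sum of per-trial densities", {
  offers <- generate_offer_set(seed = 3)
  sim <- simulate_dataset(spec_full(), anchor_params(), offers, seed = 4)
  sim <- sim[sim$choice != "timeout", ][1:5, ]
  ll <- loglik_trials(spec_full(), anchor_params(), sim)
  expect_equal(ll$total, sum(ll$per_trial))
  expect_length(ll$per_trial, 5)

  one <- loglik_trials(spec_full(), anchor_params(), sim[1, ])
  f <- compute_features(sim[1, ])
  v <- drift_rate(spec_full(), anchor_params(), f)
  expect_equal(one$total,
               wfpt_density(sim$rt_s[1],
                            if (sim$choice[1] == "reject") "upper" else "lower",
                            2.16, 0.543, 0.591, v))

  doubled <- loglik_trials(spec_full(), anchor_params(), rbind(sim, sim))
  expect_equal(doubled$total, 2 * ll$total)

  # independent oracle on the same 5 trials
  oracle <- vapply(seq_len(5), function(i) {
    v <- drift_rate(spec_full(), anchor_params(), compute_features(sim[i, ]))
    log(wfpt_density_oracle(sim$rt_s[i],
                            if (sim$choice[i] == "reject") "upper" else "lower",
                            2.16, 0.543, 0.591, v))
  }, numeric(1))
  expect_equal(ll$per_trial, oracle, tolerance = 1e-7)

  expect_error(loglik_trials(spec_full(), anchor_params(),
                             make_trials("1/9", "timeout", NA)), "timeout")
})

test_that("simulated choices follow the drift and the analytic probabilities", {
  dom <- simulate_paths(2000, 2, 0.5, 0.3, 10, seed = 1)
  expect_gte(mean(dom$choice == "reject"), 0.999)

  sym <- simulate_paths(20000, 2, 0.5, 0.3, 0, seed = 2)
  se <- sqrt(0.25 / 20000)
  expect_lt(abs(mean(sym$choice == "reject") - 0.5), 3 * se)
})

test_that("simulated datasets have the right shape and are reproducible", {
  offers <- generate_offer_set(seed = 10)
  a <- simulate_dataset(spec_full(), anchor_params(), offers, seed = 1)
  b <- simulate_dataset(spec_full(), anchor_params(), offers, seed = 1)
  c <- simulate_dataset(spec_full(), anchor_params(), offers, seed = 2)
  expect_equal(nrow(a), 56)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_true(all(a$rt_s[a$choice != "timeout"] <= 10))
})

test_that("an inequity avoider rejects 1/9 offers more often than 2/3 offers", {
  p <- ddm_params(2, 0.5, 0.5, betas = c(SR = -0.5, DI = 1, AI = 0.5))
  rates <- vapply(1:20, function(r) {
    sim <- simulate_dataset(spec_full(), p, generate_offer_set(seed = r),
                            seed = 100 + r)
    sim <- sim[sim$choice != "timeout", ]
    c(mean(sim$choice[sim$condition_label == "1/9"] == "reject"),
      mean(sim$choice[sim$condition_label == "2/3"] == "reject"))
  }, numeric(2))
  expect_gt(mean(rates[1, ]), mean(rates[2, ]))
})

test_that("mean decision time shrinks as |drift| grows and matches quadrature", {
  m <- mean_decision_time(2, 0.5, c(0, 0.5, 1, 2, 4))
  expect_true(all(diff(m) < 0))
  q <- integrate(function(t) {
    t * (wfpt_density(t, "upper", 2, 0.4, 0, 1.3, log = FALSE) +
           wfpt_density(t, "lower", 2, 0.4, 0, 1.3, log = FALSE))
  }, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(mean_decision_time(2, 0.4, 1.3), q, tolerance = 1e-7)
})
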
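test_that("degenerate and truncated population draws behave as configured", {
  cfg0 <- cohort_config(n_participants = 4, sds = c(alpha = 0, z = 0,
                                                    tau = 0, beta_SR = 0,
                                                    beta_DI = 0,
                                                    beta_AI = 0), seed = 3)
  a1 <- sample_agent(cfg0, 1)
  a2 <- sample_agent(cfg0, 2)
  expect_equal(a1$params$alpha, 2.16)
  expect_equal(a1$params$betas[["DI"]], 0.371)
  expect_equal(a1$params, a2$params)

  cfg <- cohort_config(n_participants = 200, seed = 4)
  draws <- t(vapply(1:200, function(i) {
    a <- sample_agent(cfg, i)
    c(a$params$alpha, a$params$z, a$params$tau, a$params$betas)
  }, numeric(6)))
  expect_true(all(draws[, 1] > 0))
  expect_true(all(draws[, 2] > 0 & draws[, 2] < 1))
  expect_true(all(draws[, 3] > 0))
  expect_true(all(abs(draws[, 4:6]) < 3))

  expect_error(cohort_config(means = c(alpha = -1, z = 0.5, tau = 0.5,
                                       beta_SR = 0, beta_DI = 0,
                                       beta_AI = 0),
                             sds = c(alpha = 0, z = 0.1, tau = 0.1,
                                     beta_SR = 0.1, beta_DI = 0.1,
                                     beta_AI = 0.1)),
               "impossible truncation")
})

test_that("sampled beta(DI) matches the configured population mean", {
  cfg <- cohort_config(n_participants = 3000, seed = 5)
  bdi <- vapply(1:3000, function(i) sample_agent(cfg, i)$params$betas[["DI"]],
                numeric(1))
  # truncation to (-3, 3) barely moves the mean at these moments
  se <- 0.481 / sqrt(3000)
  expect_lt(abs(mean(bdi) - 0.371), 3 * se + 0.01)
  expect_lt(abs(sd(bdi) - 0.481), 0.05)
})

test_that("a cohort emits one 56-trial table per participant plus a registry", {
  cohort <- make_cohort(cohort_config(n_participants = 5, seed = 6))
  expect_equal(nrow(cohort$trials), 5 * 56)
  expect_equal(nrow(cohort$agents), 5)
  expect_setequal(unique(cohort$trials$participant_id),
                  cohort$agents$participant_id)
  expect_true(all(c("alpha", "z", "tau", "beta_SR", "beta_DI", "beta_AI")
                  %in% names(cohort$agents)))
  # identical config regenerates identically
  cohort2 <- make_cohort(cohort_config(n_participants = 5, seed = 6))
  expect_identical(cohort$trials, cohort2$trials)
})

test_that("all-accept-like agents appear at the configured fraction", {
  cfg <- cohort_config(n_participants = 10, all_accept_fraction = 0.2,
                       seed = 7)
  aa <- vapply(1:10, function(i) attr(sample_agent(cfg, i),
                                      "all_accept_like"), logical(1))
  expect_equal(sum(aa), 2)
  a1 <- sample_agent(cfg, 1)
  expect_lt(a1$params$betas[["SR"]], -1)
  expect_lt(abs(a1$params$betas[["DI"]]), 0.3)
})

test_that("cohorts at the anchor moments show the expected group behavior", {
  cohort <- make_cohort(cohort_config(n_participants = 63, seed = 8))
  beh <- summarize_behavior(cohort$trials)
  tab <- beh$by_condition
  di_rate <- weighted.mean(tab$rejection_rate[tab$condition_class == "di"],
                           tab$n_valid[tab$condition_class == "di"])
  ai_rate <- weighted.mean(tab$rejection_rate[tab$condition_class == "ai"],
                           tab$n_valid[tab$condition_class == "ai"])
  expect_gt(di_rate, ai_rate)

  # accepting a strongly disadvantageous offer is slower than rejecting it;
  # for advantageous offers the asymmetry reverses
  expect_gt(tab$mean_rt_accept[tab$condition_label == "1/9"],
            tab$mean_rt_reject[tab$condition_label == "1/9"])
  expect_gt(tab$mean_rt_reject[tab$condition_label == "7/3"],
            tab$mean_rt_accept[tab$condition_label == "7/3"])
})
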
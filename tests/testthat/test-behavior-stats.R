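test_that("behavior summaries match a hand tally on a 14-trial table", {
  tr <- make_trials(
    c("1/9", "1/9", "1/9", "1/9", "1/4", "1/4", "3/7", "2/3",
      "1/1", "1/1", "3/2", "3/2", "7/3", "7/3"),
    c("reject", "reject", "accept", "timeout", "reject", "accept",
      "accept", "accept", "accept", "accept", "accept", "accept",
      "accept", "reject"),
    c(1.0, 2.0, 4.0, NA, 1.5, 3.5, 2.0, 1.8, 1.2, 1.4, 1.1, 1.3, 0.9, 2.5))
  beh <- summarize_behavior(tr)
  bp <- beh$by_participant
  expect_equal(nrow(bp), 7)
  r19 <- bp[bp$condition_label == "1/9", ]
  expect_equal(r19$n_valid, 3)
  expect_equal(r19$n_timeout, 1)
  expect_equal(r19$rejection_rate, 2 / 3)
  expect_equal(r19$mean_rt_reject, 1.5)
  expect_equal(r19$mean_rt_accept, 4.0)
  r73 <- bp[bp$condition_label == "7/3", ]
  expect_equal(r73$rejection_rate, 1 / 2)
  expect_equal(r73$condition_class, "ai")
  # counts conserve the total number of trials
  expect_equal(sum(bp$n_trials), nrow(tr))
  expect_equal(sum(bp$n_valid) + sum(bp$n_timeout), nrow(tr))
})

test_that("an all-accept participant has zero rates and empty reject cells", {
  tr <- make_trials(rep(base_offers()$condition_label, 2),
                    rep("accept", 14), seq(0.5, 7, by = 0.5))
  beh <- summarize_behavior(tr)
  expect_true(all(beh$by_participant$rejection_rate == 0))
  expect_true(all(is.na(beh$by_participant$mean_rt_reject)))
  expect_true(all(!is.na(beh$by_participant$mean_rt_accept)))
  expect_error(summarize_behavior(transform(tr, condition_label = "9/9")),
               "unknown condition")
})

test_that("normalized RT centers on the 1/1 condition and is shift invariant", {
  tr <- make_trials(c("1/1", "1/1", "1/9", "2/3"),
                    c("accept", "accept", "reject", "accept"),
                    c(1.0, 2.0, 3.0, 2.5))
  norm <- normalized_rt(tr)
  expect_equal(mean(norm$rt_norm_s[norm$condition_label == "1/1"]), 0)
  expect_equal(norm$rt_norm_s, c(-0.5, 0.5, 1.5, 1.0))

  shifted <- transform(tr, rt_s = rt_s + 0.5)
  expect_equal(normalized_rt(shifted)$rt_norm_s, norm$rt_norm_s)

  # three participants, hand computed
  tri <- rbind(make_trials(c("1/1", "1/9"), c("accept", "reject"),
                           c(2, 3), id = "A"),
               make_trials(c("1/1", "1/9"), c("accept", "reject"),
                           c(1, 1.5), id = "B"),
               make_trials(c("1/1", "1/4"), c("accept", "accept"),
                           c(4, 5), id = "C"))
  n3 <- normalized_rt(tri)
  expect_equal(n3$rt_norm_s, c(0, 1, 0, 0.5, 0, 1))

  no11 <- make_trials(c("1/9", "1/4"), c("accept", "accept"), c(1, 2))
  expect_error(normalized_rt(no11), "no decided 1/1")
})

test_that("Holm adjustment in correlation reports follows the step-down rule", {
  set.seed(31)
  n <- 12
  x <- rnorm(n)
  pairs <- list(
    strong = list(x = x, y = x + rnorm(n, sd = 0.2)),
    medium = list(x = x, y = x + rnorm(n, sd = 1.5)),
    none = list(x = x, y = rnorm(n)),
    flat = list(x = x, y = rep(1, n)) # undefined, must be excluded
  )
  rep_ <- suppressWarnings(pearson_holm(pairs))
  expect_equal(nrow(rep_), 4)
  expect_false(rep_$defined[rep_$pair == "flat"])
  ok <- rep_$defined
  expect_equal(rep_$p_holm[ok], manual_holm(rep_$p_value[ok]))
  expect_true(all(rep_$p_holm[ok] >= rep_$p_value[ok]))
  expect_true(all(rep_$p_holm[ok] <= 1))
  # adjusted values are monotone in the raw ordering
  o <- order(rep_$p_value[ok])
  expect_true(all(diff(rep_$p_holm[ok][o]) >= 0))

  lin <- pearson_holm(list(exact = list(x = 1:10, y = 2 * (1:10) + 3)))
  expect_equal(lin$r, 1)
  expect_lt(lin$p_value, 1e-12)
})

test_that("drift-behavior correlations recover the mechanistic associations", {
  cohort <- make_cohort(cohort_config(n_participants = 40, seed = 13))
  beh <- summarize_behavior(cohort$trials)
  corr <- drift_behavior_correlations(cohort$agents, beh)
  expect_equal(nrow(corr), 6)
  expect_true(all(corr$defined))
  # inequity aversion drives rejection of disadvantageous offers, and the
  # advantageous-inequity coefficient drives rejection of advantageous ones
  expect_gt(corr$r[corr$pair == "beta_DI_vs_rejection_DI"], 0.5)
  expect_lt(corr$p_holm[corr$pair == "beta_DI_vs_rejection_DI"], 0.05)
  expect_gt(corr$r[corr$pair == "beta_AI_vs_rejection_AI"], 0)
})

test_that("correlation-family inputs are validated", {
  est <- data.frame(participant_id = c("A", "B"), beta_SR = c(-1, -0.5),
                    beta_DI = c(0.5, 1), beta_AI = c(0, 0.2))
  tr <- rbind(make_trials("1/9", "reject", 1, id = "A"),
              make_trials("1/9", "accept", 2, id = "B"))
  expect_error(drift_behavior_correlations(est, summarize_behavior(tr)),
               "at least 3")
  est3 <- rbind(est, data.frame(participant_id = "C", beta_SR = 0,
                                beta_DI = 0, beta_AI = 0))
  expect_error(drift_behavior_correlations(est3, summarize_behavior(tr)),
               "do not match")
})
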
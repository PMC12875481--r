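test_that("an offer set has 56 trials, 8 per condition, jittered on the grid", {
  offers <- generate_offer_set(seed = 0)
  expect_equal(nrow(offers), 56)
  expect_true(all(table(offers$condition_label) == 8))
  expect_equal(sum(offers$condition_label == "1/9"), 8)

  base <- base_offers()
  idx <- match(offers$condition_label, base$condition_label)
  jit_sr <- offers$sr_yen - base$sr_yen[idx]
  jit_or <- offers$or_yen - base$or_yen[idx]
  expect_true(all(abs(jit_sr) <= 25, abs(jit_or) <= 25))
  expect_true(all(jit_sr %% 5 == 0, jit_or %% 5 == 0))
})

test_that("offer generation is deterministic and zero jitter reproduces the base pairs", {
  expect_identical(generate_offer_set(seed = 7), generate_offer_set(seed = 7))
  expect_false(identical(generate_offer_set(seed = 7),
                         generate_offer_set(seed = 8)))

  plain <- generate_offer_set(seed = 0, jitter_max_yen = 0)
  counts <- table(paste(plain$sr_yen, plain$or_yen))
  base <- base_offers()
  expect_setequal(names(counts), paste(base$sr_yen, base$or_yen))
  expect_true(all(counts == 8))
})

test_that("inequity features follow the max() definitions", {
  f <- compute_features(data.frame(sr_yen = 50, or_yen = 450), scale_yen = 100)
  expect_equal(f$sr, 0.5)
  expect_equal(f$di, 4.0)
  expect_equal(f$ai, 0.0)

  f <- compute_features(data.frame(sr_yen = 250, or_yen = 250))
  expect_equal(c(f$di, f$ai), c(0, 0))

  f <- compute_features(data.frame(sr_yen = 350, or_yen = 150))
  expect_equal(f$di, 0)
  expect_equal(f$ai, 2.0)

  expect_error(compute_features(data.frame(sr_yen = -10, or_yen = 100)),
               "negative")
})

test_that("signed inequity identity di - ai = or - sr holds on generated offers", {
  for (seed in 1:5) {
    f <- compute_features(generate_offer_set(seed = seed))
    expect_equal(f$di - f$ai, f$or_ - f$sr)
    expect_true(all(f$di >= 0, f$ai >= 0, f$di * f$ai == 0))
  }
})

test_that("trial tables round-trip through CSV", {
  tr <- make_trials(c("1/9", "1/1", "7/3"),
                    c("reject", "accept", "timeout"),
                    c(1.25, 2.5, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  cols <- c("participant_id", "trial_index", "condition_label", "sr_yen",
            "or_yen", "choice", "rt_s")
  expect_equal(back[, cols], tr[, cols], ignore_attr = TRUE)
  expect_equal(back$excluded_from_fit, c(FALSE, FALSE, TRUE))
})

test_that("malformed trial rows are rejected with row numbers", {
  tr <- make_trials("1/9", "reject", 12.0)
  expect_error(validate_trials(tr), "row 1.*deadline")
  tr2 <- make_trials("1/9", "maybe", 1.0)
  expect_error(validate_trials(tr2), "unknown choice token.*row 1")

  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(participant_id = "P1", trial_index = 0), path,
            row.names = FALSE)
  expect_error(read_trials(path), "missing column")
})

test_that("timeout rows are kept but flagged excluded from fitting", {
  tr <- make_trials(c("1/9", "1/9"), c("timeout", "accept"), c(NA, 3))
  v <- validate_trials(tr)
  expect_equal(nrow(v), 2)
  expect_true(v$excluded_from_fit[1])
  expect_true(is.na(v$rt_s[1]))
})

test_that("VIF is 1 for orthogonal designs and Inf under exact collinearity", {
  X <- data.frame(a = rep(c(-1, 1), each = 4),
                  b = rep(c(-1, 1), times = 4),
                  c = rep(c(-1, 1, 1, -1), times = 2))
  d <- design_diagnostics(X, regressors = c("a", "b", "c"))
  expect_equal(unname(d$vif), c(1, 1, 1))
  expect_equal(diag(d$correlation_matrix), c(a = 1, b = 1, c = 1))

  X$b <- X$a
  d2 <- design_diagnostics(X, regressors = c("a", "b", "c"))
  expect_true(is.infinite(d2$vif[["a"]]))
  expect_true(is.infinite(d2$vif[["b"]]))
})

test_that("VIFs match the correlation-matrix-inverse oracle on a random design", {
  set.seed(42)
  X <- data.frame(x1 = rnorm(10), x2 = rnorm(10), x3 = rnorm(10))
  X$x2 <- X$x2 + 0.8 * X$x1 # induce collinearity
  d <- design_diagnostics(X, regressors = c("x1", "x2", "x3"))
  oracle <- diag(solve(cor(X))) # standardized-design identity
  expect_equal(unname(d$vif), unname(oracle), tolerance = 1e-10)
  expect_true(all(d$vif >= 1))
})

test_that("degenerate designs are refused with the offending regressor named", {
  X <- data.frame(a = rnorm(10), b = rnorm(10), c = rep(2, 10))
  expect_error(design_diagnostics(X, c("a", "b", "c")), "zero-variance.*c")
  expect_error(design_diagnostics(X[1:3, c(1, 2)], c("a", "b")),
               "at least 4")
})
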
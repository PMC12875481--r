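# Shared fixtures, built in code at test time.

# Group-level anchor parameters of the full SR+AI+DI model.
anchor_params <- function() {
  ddm_params(2.16, 0.543, 0.591,
             betas = c(SR = -0.930, DI = 0.371, AI = 0.254))
}

spec_full <- function() drift_spec(c("SR", "AI", "DI"))

# A reduced-setting posterior fit for unit tests.
quick_fit <- function(trials, spec = spec_full(), seed = 1, chains = 2,
                      burn_in = 300, draws = 300) {
  fit_ddm(trials, spec, chains = chains, burn_in = burn_in, draws = draws,
          seed = seed)
}

# Build a small trial table by hand.
make_trials <- function(condition_label, choice, rt_s, id = "P1") {
  base <- base_offers()
  idx <- match(condition_label, base$condition_label)
  data.frame(participant_id = rep(id, length(condition_label)),
             trial_index = seq_along(condition_label) - 1L,
             condition_label = condition_label,
             sr_yen = base$sr_yen[idx], or_yen = base$or_yen[idx],
             choice = choice, rt_s = rt_s, stringsAsFactors = FALSE)
}

# Independent slow implementation of the Wiener FPT density at the lower
# boundary: plain image sum with a fixed, large number of terms (no
# small/large-time switching), used as an oracle.
wfpt_lower_image_sum <- function(t, v, a, w, tau, K = 150) {
  td <- t - tau
  if (td <= 0) return(0)
  u <- td / a^2
  k <- -K:K
  s <- sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * u)))
  s / sqrt(2 * pi * u^3) * exp(-v * a * w - v^2 * td / 2) / a^2
}

wfpt_density_oracle <- function(t, boundary, alpha, z, tau, drift) {
  if (boundary == "upper") {
    wfpt_lower_image_sum(t, -drift, alpha, 1 - z, tau)
  } else {
    wfpt_lower_image_sum(t, drift, alpha, z, tau)
  }
}

# Independent Holm step-down adjustment.
manual_holm <- function(p) {
  o <- order(p)
  m <- length(p)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
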
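#' Simulate a single DDM trial
#'
#' Euler-Maruyama simulation of the diffusion started at `z * alpha`,
#' absorbed at 0 (accept) or `alpha` (reject); the response time is the
#' first-passage time plus nondecision time. If the response time would
#' exceed the deadline the trial is censored as a timeout.
#'
#' @param alpha,z,tau DDM parameters (see [ddm_params()]).
#' @param drift Drift rate of the trial.
#' @param seed Optional integer seed for reproducibility.
#' @param deadline_s Response deadline in seconds (default 10).
#' @param dt Euler step in seconds (default `1e-4`).
#' @return A list with `choice` (`"accept"`, `"reject"` or `"timeout"`) and
#'   `rt_s` (NA on timeout).
#' @export
simulate_trial <- function(alpha, z, tau, drift, seed = NULL,
                           deadline_s = 10, dt = 1e-4) {
  stopifnot(alpha > 0, z > 0, z < 1, tau >= 0, dt <= 1e-3, dt > 0)
  run <- function() cpp_simulate_ddm(drift, alpha, z, tau, dt, deadline_s)
  sim <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  list(choice = c("accept", "reject", "timeout")[sim$choice + 1L],
       rt_s = sim$rt[1])
}

#' Simulate a full trial dataset from DDM parameters
#'
#' Simulates one trial per offer under the given drift specification and
#' parameters, producing a trial table in the canonical dialect. Each trial
#' is seeded from `(seed, trial index)` so datasets are reproducible and
#' stable under reordering of computations.
#'
#' @param spec A [drift_spec()].
#' @param params A [ddm_params()].
#' @param offers An offer data.frame (see [generate_offer_set()]).
#' @param seed Integer seed.
#' @param participant_id Identifier stamped on every row.
#' @param scale_yen Yen per model unit (default 100).
#' @param deadline_s Response deadline (default 10 s).
#' @param dt Euler step (default `1e-4` s).
#' @return A trial data.frame with simulated `choice` and `rt_s`.
#' @examples
#' offers <- generate_offer_set(seed = 1)
#' p <- ddm_params(2.16, 0.543, 0.591,
#'                 betas = c(SR = -0.930, DI = 0.371, AI = 0.254))
#' sim <- simulate_dataset(drift_spec(c("SR", "DI", "AI")), p, offers,
#'                         seed = 1)
#' table(sim$choice)
#' @export
simulate_dataset <- function(spec, params, offers, seed,
                             participant_id = "sim", scale_yen = 100,
                             deadline_s = 10, dt = 1e-4) {
  stopifnot(inherits(spec, "drift_spec"), inherits(params, "ddm_params"))
  feats <- compute_features(offers, scale_yen)
  v <- drift_rate(spec, params, feats)
  # stable per-trial-index seeding: trial i is unaffected by other trials
  sims <- lapply(seq_along(v), function(i) {
    withr::with_seed(derive_seed(seed, i), {
      cpp_simulate_ddm(v[i], params$alpha, params$z, params$tau, dt,
                       deadline_s)
    })
  })
  sim <- list(choice = vapply(sims, function(s) s$choice[1], integer(1)),
              rt = vapply(sims, function(s) s$rt[1], numeric(1)))
  out <- data.frame(
    participant_id = participant_id,
    trial_index = seq_len(nrow(offers)) - 1L,
    condition_label = if (is.null(offers$condition_label)) {
      infer_condition_label(offers$sr_yen, offers$or_yen)
    } else {
      offers$condition_label
    },
    sr_yen = offers$sr_yen,
    or_yen = offers$or_yen,
    choice = c("accept", "reject", "timeout")[sim$choice + 1L],
    rt_s = round(sim$rt, 4),
    stringsAsFactors = FALSE
  )
  validate_trials(out, deadline_s = deadline_s)
}

#' Simulate many first-passage paths at fixed parameters
#'
#' Vectorized Monte-Carlo simulation of `n` independent trials at a single
#' drift value, used for density/probability cross-checks and
#' posterior-predictive summaries.
#'
#' @inheritParams simulate_trial
#' @param n Number of paths.
#' @return A data.frame with columns `choice` and `rt_s`.
#' @export
simulate_paths <- function(n, alpha, z, tau, drift, seed,
                           deadline_s = 10, dt = 1e-4) {
  stopifnot(n >= 1, dt > 0, dt <= 1e-3)
  sim <- withr::with_seed(as.integer(seed), {
    cpp_simulate_ddm(rep(drift, n), alpha, z, tau, dt, deadline_s)
  })
  data.frame(choice = c("accept", "reject", "timeout")[sim$choice + 1L],
             rt_s = sim$rt)
}
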
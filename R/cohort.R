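#' Configuration of a synthetic cohort
#'
#' Describes a population of simulated responders whose DDM parameters are
#' drawn from independent truncated normals. The default moments anchor the
#' population to the group-level means and standard deviations of the
#' estimated parameters under the full `SR+AI+DI` drift model (boundary
#' 2.16 +/- 0.680, bias 0.543 +/- 0.0962, nondecision time 0.591 +/- 0.266 s,
#' beta(SR) -0.930 +/- 0.504, beta(DI) 0.371 +/- 0.481, beta(AI)
#' 0.254 +/- 0.868). A configurable fraction of "all-accept-like" agents
#' (near-zero beta(DI), strongly negative beta(SR)) can be mixed in to
#' emulate responders who accept every offer.
#'
#' @param n_participants Cohort size (default 63).
#' @param means,sds Named numeric vectors over `alpha`, `z`, `tau`,
#'   `beta_SR`, `beta_DI`, `beta_AI`.
#' @param all_accept_fraction Fraction of all-accept-like agents (default 0).
#' @param all_accept_means,all_accept_sds Moments of the all-accept-like
#'   subpopulation.
#' @param spec Drift specification used to generate behavior.
#' @param seed Master seed.
#' @param scale_yen Yen per model unit.
#' @param jitter_step_yen Offer jitter grid step.
#' @param dt Euler step of the trial simulator.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 63,
                          means = c(alpha = 2.16, z = 0.543, tau = 0.591,
                                    beta_SR = -0.930, beta_DI = 0.371,
                                    beta_AI = 0.254),
                          sds = c(alpha = 0.680, z = 0.0962, tau = 0.266,
                                  beta_SR = 0.504, beta_DI = 0.481,
                                  beta_AI = 0.868),
                          all_accept_fraction = 0,
                          all_accept_means = c(alpha = 2.16, z = 0.45,
                                               tau = 0.591, beta_SR = -2,
                                               beta_DI = 0, beta_AI = 0),
                          all_accept_sds = c(alpha = 0.4, z = 0.05,
                                             tau = 0.15, beta_SR = 0.3,
                                             beta_DI = 0.05, beta_AI = 0.05),
                          spec = drift_spec(c("SR", "AI", "DI")),
                          seed = 1, scale_yen = 100, jitter_step_yen = 5,
                          dt = 1e-4) {
  par_names <- c("alpha", "z", "tau", "beta_SR", "beta_DI", "beta_AI")
  stopifnot(n_participants >= 1, all(par_names %in% names(means)),
            all(par_names %in% names(sds)), all(sds >= 0),
            all_accept_fraction >= 0, all_accept_fraction <= 1)
  sup <- param_supports()
  for (nm in par_names) {
    if (sds[nm] == 0 &&
        (means[nm] <= sup[[nm]][1] || means[nm] >= sup[[nm]][2])) {
      stop("impossible truncation: mean of ", nm,
           " lies outside its support with SD 0")
    }
  }
  structure(list(n_participants = n_participants, means = means[par_names],
                 sds = sds[par_names],
                 all_accept_fraction = all_accept_fraction,
                 all_accept_means = all_accept_means[par_names],
                 all_accept_sds = all_accept_sds[par_names],
                 spec = spec, seed = seed, scale_yen = scale_yen,
                 jitter_step_yen = jitter_step_yen, dt = dt),
            class = "cohort_config")
}

# Valid supports of each population parameter (open intervals).
param_supports <- function() {
  list(alpha = c(0, Inf), z = c(0, 1), tau = c(0, Inf),
       beta_SR = c(-3, 3), beta_DI = c(-3, 3), beta_AI = c(-3, 3))
}

# One truncated-normal draw by rejection sampling.
rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd == 0) return(mean)
  for (i in 1:10000) {
    x <- rnorm(1, mean, sd)
    if (x > lower && x < upper) return(x)
  }
  stop("truncated-normal sampling failed: mean ", mean, ", sd ", sd)
}

#' Draw one ground-truth agent from a cohort configuration
#'
#' Each parameter is drawn from a truncated normal with the configured
#' moments, restricted to its valid support (`alpha, tau > 0`, `z` in (0,1),
#' betas in (-3, 3)). Deterministic given `(seed, participant_index)`.
#'
#' @param config A [cohort_config()].
#' @param participant_index 1-based index within the cohort.
#' @return An [agent_spec()] (label `"custom"`), with the participant's
#'   id in attribute `"participant_id"`.
#' @export
sample_agent <- function(config, participant_index) {
  stopifnot(inherits(config, "cohort_config"),
            participant_index >= 1,
            participant_index <= config$n_participants)
  n_aa <- round(config$all_accept_fraction * config$n_participants)
  is_aa <- participant_index <= n_aa
  means <- if (is_aa) config$all_accept_means else config$means
  sds <- if (is_aa) config$all_accept_sds else config$sds
  sup <- param_supports()
  th <- withr::with_seed(derive_seed(config$seed, participant_index), {
    vapply(names(means), function(nm) {
      rtruncnorm1(means[[nm]], sds[[nm]], sup[[nm]][1], sup[[nm]][2])
    }, numeric(1))
  })
  params <- ddm_params(th[["alpha"]], th[["z"]], th[["tau"]],
                       betas = c(SR = th[["beta_SR"]], AI = th[["beta_AI"]],
                                 DI = th[["beta_DI"]]))
  agent <- agent_spec("custom", params = params, spec = config$spec)
  attr(agent, "participant_id") <- sprintf("P%03d", participant_index)
  attr(agent, "all_accept_like") <- is_aa
  agent
}

#' Generate a synthetic cohort of trial tables
#'
#' For every participant: draw ground-truth parameters from the population
#' model, generate a fresh 56-trial jittered offer set, and simulate choices
#' and response times with the trial simulator under the 10-s deadline.
#' Returns the pooled trial table together with the ground-truth registry
#' needed for end-to-end recovery checks.
#'
#' @param config A [cohort_config()].
#' @return Object of class `ug_cohort`: list with `trials` (canonical trial
#'   table) and `agents` (data.frame of true parameters per participant).
#' @examples
#' \donttest{
#' cohort <- make_cohort(cohort_config(n_participants = 3, seed = 7))
#' table(cohort$trials$participant_id)
#' }
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  trials <- list()
  agents <- list()
  for (i in seq_len(config$n_participants)) {
    agent <- sample_agent(config, i)
    id <- attr(agent, "participant_id")
    offers <- generate_offer_set(derive_seed(config$seed, 70000 + i),
                                 jitter_step_yen = config$jitter_step_yen)
    trials[[i]] <- simulate_dataset(
      config$spec, agent$params, offers,
      seed = derive_seed(config$seed, 140000 + i), participant_id = id,
      scale_yen = config$scale_yen, dt = config$dt)
    agents[[i]] <- data.frame(
      participant_id = id, all_accept_like = attr(agent, "all_accept_like"),
      alpha = agent$params$alpha, z = agent$params$z, tau = agent$params$tau,
      beta_SR = unname(agent$params$betas["SR"]),
      beta_DI = unname(agent$params$betas["DI"]),
      beta_AI = unname(agent$params$betas["AI"]),
      stringsAsFactors = FALSE)
  }
  structure(list(trials = do.call(rbind, trials),
                 agents = do.call(rbind, agents), config = config),
            class = "ug_cohort")
}

#' @export
print.ug_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants x %d trials (%d timeouts)\n",
              nrow(x$agents), sum(x$agents$participant_id[1] ==
                                    x$trials$participant_id),
              sum(x$trials$choice == "timeout")))
  invisible(x)
}
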
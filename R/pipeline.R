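#' End-to-end run configuration
#'
#' A single configuration object for the full analysis run: where the trials
#' come from (a CSV path or the synthetic cohort generator), which drift
#' specifications to consider (`"select"` ranks all nine), sampler settings,
#' and the master seed from which every stage's seed is derived. The
#' configuration round-trips losslessly through JSON via
#' [write_run_config()] / [read_run_config()].
#'
#' @param output_dir Directory for all stage outputs.
#' @param trials_path Optional path to an existing trial-table CSV.
#' @param cohort A [cohort_config()] used when `trials_path` is `NULL`, or
#'   `NULL` to disable generation.
#' @param spec `"select"` or a drift-spec label (e.g. `"SR+AI+DI"`).
#' @param chains,burn_in,draws Sampler settings.
#' @param recovery_repeats Repeats for the recovery stage (0 disables).
#' @param cv_participants How many participants get the RT cross-validation
#'   stage (0 disables; they are taken in table order).
#' @param seed Master seed.
#' @param scale_yen Yen per model unit.
#' @return Object of class `run_config`.
#' @export
run_config <- function(output_dir, trials_path = NULL,
                       cohort = cohort_config(), spec = "select",
                       chains = 4, burn_in = 2000, draws = 2000,
                       recovery_repeats = 0, cv_participants = 0,
                       seed = 1, scale_yen = 100) {
  stopifnot(is.character(output_dir), scale_yen > 0, chains >= 1)
  if (is.null(trials_path) && is.null(cohort)) {
    stop("no input: `trials_path` is NULL and cohort generation is disabled")
  }
  labels <- c(names(drift_specs()), "select")
  if (!spec %in% labels) {
    stop("`spec` must be \"select\" or one of: ",
         paste(names(drift_specs()), collapse = ", "))
  }
  structure(list(output_dir = output_dir, trials_path = trials_path,
                 cohort = cohort, spec = spec, chains = chains,
                 burn_in = burn_in, draws = draws,
                 recovery_repeats = recovery_repeats,
                 cv_participants = cv_participants, seed = seed,
                 scale_yen = scale_yen),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `read_run_config()` returns the restored `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  if (!is.null(x$cohort)) {
    x$cohort <- unclass(x$cohort)
    x$cohort$spec <- x$cohort$spec$label
    for (nm in c("means", "sds", "all_accept_means", "all_accept_sds")) {
      x$cohort[[nm]] <- as.list(x$cohort[[nm]]) # keep names in JSON
    }
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x[c("output_dir", "trials_path", "spec")] <-
    lapply(x[c("output_dir", "trials_path", "spec")],
           function(v) if (is.null(v)) NULL else as.character(v))
  for (nm in c("chains", "burn_in", "draws", "recovery_repeats",
               "cv_participants", "seed", "scale_yen")) {
    x[[nm]] <- as.numeric(x[[nm]])
  }
  cohort <- if (is.null(x$cohort)) NULL else {
    cc <- x$cohort
    lbl <- as.character(cc$spec)
    for (nm in c("n_participants", "all_accept_fraction", "seed",
                 "scale_yen", "jitter_step_yen", "dt")) {
      cc[[nm]] <- as.numeric(cc[[nm]])
    }
    cohort_config(n_participants = cc$n_participants,
                  means = unlist(cc$means), sds = unlist(cc$sds),
                  all_accept_fraction = cc$all_accept_fraction,
                  all_accept_means = unlist(cc$all_accept_means),
                  all_accept_sds = unlist(cc$all_accept_sds),
                  spec = drift_specs()[[lbl]], seed = cc$seed,
                  scale_yen = cc$scale_yen,
                  jitter_step_yen = cc$jitter_step_yen, dt = cc$dt)
  }
  run_config(output_dir = x$output_dir, trials_path = x$trials_path,
             cohort = cohort, spec = x$spec, chains = x$chains,
             burn_in = x$burn_in, draws = x$draws,
             recovery_repeats = x$recovery_repeats,
             cv_participants = x$cv_participants, seed = x$seed,
             scale_yen = x$scale_yen)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: trial ingestion (or synthetic-cohort generation),
#' WAIC model selection (when requested), best-model fitting per participant
#' with convergence diagnostics, behavioral summaries and the
#' drift-vs-behavior correlation family, optional parameter recovery and
#' optional RT cross-validation. Every stage writes CSV/JSON outputs under
#' the configured directory and the run ends with a manifest of stage
#' outputs and their MD5 hashes; identical configurations give identical
#' hashes.
#'
#' @param config A [run_config()].
#' @return The run manifest (class `run_manifest`), also written as
#'   `manifest.json`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  stages <- list()
  step <- function(name, f) {
    res <- tryCatch(f(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages[[name]] <<- res
    res
  }

  # --- trials ---
  trials <- step("trials", function() {
    if (!is.null(config$trials_path)) {
      tr <- read_trials(config$trials_path)
      write_trials(tr, out("trials.csv"))
      tr
    } else {
      cohort <- make_cohort(config$cohort)
      write_trials(cohort$trials, out("trials.csv"))
      write.csv(cohort$agents, out("agents_truth.csv"), row.names = FALSE)
      cohort$trials
    }
  })

  # --- model selection ---
  best_label <- config$spec
  selection <- NULL
  if (config$spec == "select") {
    selection <- step("selection", function() {
      sel <- run_selection(trials, priors = prior_spec(),
                           chains = config$chains, burn_in = config$burn_in,
                           draws = config$draws,
                           seed = derive_seed(config$seed, 1),
                           scale_yen = config$scale_yen)
      write.csv(sel$table, out("model_table.csv"), row.names = FALSE)
      sel
    })
    best_label <- selection$best_spec
  }
  best <- drift_specs()[[best_label]]

  # --- best-model fits ---
  fits <- step("fits", function() {
    ids <- unique(trials$participant_id)
    fits <- lapply(seq_along(ids), function(i) {
      fit_ddm(trials[trials$participant_id == ids[i], ], best,
              chains = config$chains, burn_in = config$burn_in,
              draws = config$draws, seed = derive_seed(config$seed, 100 + i),
              scale_yen = config$scale_yen)
    })
    names(fits) <- ids
    est <- do.call(rbind, lapply(ids, function(id) {
      m <- posterior_means(fits[[id]])
      cbind(data.frame(participant_id = id), as.data.frame(t(m)))
    }))
    rhat <- vapply(fits, function(f) max(gelman_rubin(f)$rhat), numeric(1))
    est$max_rhat <- rhat
    write.csv(est, out("estimates.csv"), row.names = FALSE)
    list(fits = fits, estimates = est)
  })

  # --- behavior + correlations ---
  step("behavior", function() {
    beh <- summarize_behavior(trials)
    write.csv(beh$by_condition, out("behavior_by_condition.csv"),
              row.names = FALSE)
    write.csv(beh$by_participant, out("behavior_by_participant.csv"),
              row.names = FALSE)
    corr <- if (length(unique(trials$participant_id)) >= 3 &&
                !best$constant_only &&
                all(c("beta_SR", "beta_DI", "beta_AI") %in%
                      names(fits$estimates))) {
      drift_behavior_correlations(fits$estimates, beh)
    } else NULL
    if (!is.null(corr)) {
      write.csv(as.data.frame(corr), out("drift_behavior_correlations.csv"),
                row.names = FALSE)
    }
    list(behavior = beh, correlations = corr)
  })

  # --- recovery ---
  if (config$recovery_repeats > 0) {
    step("recovery", function() {
      recs <- lapply(c("reward_seeker", "inequity_avoider"), function(lbl) {
        rec <- parameter_recovery(agent_spec(lbl),
                                  n_repeats = config$recovery_repeats,
                                  chains = config$chains,
                                  burn_in = config$burn_in,
                                  draws = config$draws,
                                  seed = derive_seed(config$seed, 5000),
                                  scale_yen = config$scale_yen)
        data.frame(agent = lbl, parameter = names(rec$truth),
                   truth = rec$truth, bias = rec$bias, rmse = rec$rmse,
                   row.names = NULL)
      })
      df <- do.call(rbind, recs)
      write.csv(df, out("recovery.csv"), row.names = FALSE)
      df
    })
  }

  # --- RT cross-validation ---
  if (config$cv_participants > 0) {
    step("crossval", function() {
      ids <- head(unique(trials$participant_id), config$cv_participants)
      cvs <- lapply(seq_along(ids), function(i) {
        cv <- tryCatch(
          loo_cv_rt(trials[trials$participant_id == ids[i], ], best,
                    chains = config$chains, burn_in = config$burn_in,
                    draws = config$draws,
                    seed = derive_seed(config$seed, 9000 + i),
                    scale_yen = config$scale_yen),
          error = function(e) NULL)
        if (is.null(cv)) return(NULL)
        cbind(participant_id = ids[i], cv$by_condition)
      })
      df <- do.call(rbind, cvs)
      if (!is.null(df)) write.csv(df, out("crossval.csv"), row.names = FALSE)
      df
    })
  }

  files <- list.files(config$output_dir, pattern = "\\.csv$",
                      full.names = TRUE)
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("ugddm")),
    seed = config$seed, spec = best_label,
    stages = names(stages),
    outputs = setNames(as.vector(tools::md5sum(files)), basename(files)),
    config_path = {
      write_run_config(config, out("config.json"))
      "config.json"
    }
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Render a human-readable run report
#'
#' Summarizes a completed run from its manifest and output files: the model
#' table, best-spec parameter estimates with convergence, recovery
#' bias/RMSE, cross-validation correlations, and the drift-vs-behavior
#' correlation family. Stages absent from the manifest are flagged as
#' skipped. Regenerating the report does not alter any output.
#'
#' @param manifest A `run_manifest` (from [run_full()]) or the path to a
#'   `manifest.json`.
#' @param output_dir Directory holding the run outputs; defaults to the
#'   directory of the manifest file when a path is given.
#' @return Character vector of report lines, invisibly; printed to the
#'   console.
#' @export
report <- function(manifest, output_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(output_dir)) output_dir <- dirname(manifest)
    manifest <- structure(jsonlite::read_json(manifest,
                                              simplifyVector = TRUE),
                          class = "run_manifest")
  }
  if (is.null(output_dir)) {
    stop("`output_dir` is required when passing a manifest object")
  }
  lines <- c(sprintf("ugddm run report (package %s, seed %s)",
                     manifest$package_version, manifest$seed),
             sprintf("Best drift specification: %s", manifest$spec))
  show_csv <- function(file, title) {
    path <- file.path(output_dir, file)
    if (file.exists(path)) {
      df <- read.csv(path)
      c(title, utils::capture.output(print(df, row.names = FALSE)))
    } else {
      NULL
    }
  }
  all_stages <- c("trials", "selection", "fits", "behavior", "recovery",
                  "crossval")
  missing <- setdiff(all_stages, manifest$stages)
  lines <- c(lines,
             show_csv("model_table.csv", "-- Model selection (WAIC) --"),
             show_csv("estimates.csv", "-- Posterior-mean estimates --"),
             show_csv("behavior_by_condition.csv", "-- Behavior --"),
             show_csv("recovery.csv", "-- Parameter recovery --"),
             show_csv("crossval.csv", "-- RT cross-validation --"),
             show_csv("drift_behavior_correlations.csv",
                      "-- Drift vs behavior correlations --"))
  if (length(missing) > 0) {
    lines <- c(lines, paste("Skipped stages:", paste(missing,
                                                     collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest: stages", paste(x$stages, collapse = ", "), "\n")
  cat("  best spec:", x$spec, "| seed:", x$seed, "\n")
  cat("  outputs:", paste(names(x$outputs), collapse = ", "), "\n")
  invisible(x)
}
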
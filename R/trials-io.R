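#' Read a trial table from CSV
#'
#' The canonical trial-table dialect has one row per trial with columns
#' `participant_id`, `trial_index` (0-based), `sr_yen`, `or_yen`, `choice`
#' (`accept`, `reject` or `timeout`) and `rt_s` (seconds; empty on timeout
#' trials). An optional `condition_label` column is honoured; when absent the
#' label is inferred from the nearest base offer. Timeout trials are retained
#' in the table but are excluded from every likelihood downstream.
#'
#' @param path Path to a CSV file.
#' @return A validated trial data.frame with a `condition_label` column.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial table not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
  required <- c("participant_id", "trial_index", "sr_yen", "or_yen",
                "choice", "rt_s")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  validate_trials(raw, source = path)
}

#' Write a trial table to CSV
#'
#' @param trials A trial data.frame (see [read_trials()] for the dialect).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  cols <- c("participant_id", "trial_index", "condition_label",
            "sr_yen", "or_yen", "choice", "rt_s")
  write.csv(trials[, cols], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a trial table
#'
#' Enforces the trial-record invariants: known choice tokens, response times
#' inside the (0, 10] second response window for decided trials, and no
#' response time on timeout trials. Malformed rows are reported by row
#' number.
#'
#' @param trials A data.frame of trials.
#' @param deadline_s Response deadline in seconds (default 10).
#' @param source Optional label (e.g. a file path) used in error messages.
#' @return The validated data.frame, with `condition_label` filled in if
#'   absent.
#' @export
validate_trials <- function(trials, deadline_s = 10, source = NULL) {
  stopifnot(is.data.frame(trials))
  where <- if (is.null(source)) "" else paste0(" in ", source)
  bad_choice <- which(!trials$choice %in% c("accept", "reject", "timeout"))
  if (length(bad_choice) > 0) {
    stop("unknown choice token '", trials$choice[bad_choice[1]], "' at row ",
         bad_choice[1], where)
  }
  timeout <- trials$choice == "timeout"
  rt <- suppressWarnings(as.numeric(trials$rt_s))
  bad_rt <- which(!timeout & (!is.finite(rt) | rt <= 0 | rt > deadline_s))
  if (length(bad_rt) > 0) {
    stop("row ", bad_rt[1], where, ": rt_s must lie in (0, ", deadline_s,
         "] s (the response deadline) for decided trials")
  }
  rt[timeout] <- NA_real_
  trials$rt_s <- rt
  if (is.null(trials$condition_label)) {
    trials$condition_label <- infer_condition_label(trials$sr_yen,
                                                    trials$or_yen)
  }
  trials$excluded_from_fit <- timeout
  trials
}

# Trials usable in a likelihood (decided within the deadline).
valid_trials <- function(trials) {
  trials[trials$choice != "timeout", , drop = FALSE]
}
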
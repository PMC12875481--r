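#' Condition-wise behavioral summary
#'
#' Rejection rates and choice-conditional mean response times per condition,
#' both per participant and aggregated over the group (participant means of
#' the per-participant values). Cells with no trials of the relevant choice
#' are explicit missing values, never zeros. Conditions are classified from
#' the base condition label: self:other ratio below 1 is a DI condition,
#' above 1 an AI condition.
#'
#' @param trials A trial data.frame (any number of participants).
#' @return Object of class `behavior_summary`: `by_participant` and
#'   `by_condition` data.frames.
#' @export
summarize_behavior <- function(trials) {
  trials <- validate_trials(trials)
  classes <- condition_classes()
  unknown <- setdiff(unique(trials$condition_label), names(classes))
  if (length(unknown) > 0) {
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  }
  ids <- unique(trials$participant_id)
  conds <- base_offers()$condition_label
  rows <- list()
  for (id in ids) {
    for (cl in conds) {
      tr <- trials[trials$participant_id == id &
                     trials$condition_label == cl, ]
      dec <- tr[tr$choice != "timeout", ]
      acc <- dec$rt_s[dec$choice == "accept"]
      rej <- dec$rt_s[dec$choice == "reject"]
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = id, condition_label = cl,
        condition_class = unname(classes[cl]),
        n_trials = nrow(tr), n_valid = nrow(dec),
        n_timeout = sum(tr$choice == "timeout"),
        n_reject = length(rej),
        rejection_rate = if (nrow(dec) == 0) NA_real_
          else length(rej) / nrow(dec),
        mean_rt_accept = if (length(acc) == 0) NA_real_ else mean(acc),
        mean_rt_reject = if (length(rej) == 0) NA_real_ else mean(rej),
        stringsAsFactors = FALSE)
    }
  }
  by_participant <- do.call(rbind, rows)
  by_condition <- condition_table(trials)
  structure(list(by_participant = by_participant,
                 by_condition = by_condition),
            class = "behavior_summary")
}

# Group-level condition table pooled over all rows of a trial table.
condition_table <- function(trials) {
  conds <- base_offers()$condition_label
  classes <- condition_classes()
  do.call(rbind, lapply(conds, function(cl) {
    tr <- trials[trials$condition_label == cl, ]
    dec <- tr[tr$choice != "timeout", ]
    acc <- dec$rt_s[dec$choice == "accept"]
    rej <- dec$rt_s[dec$choice == "reject"]
    data.frame(
      condition_label = cl, condition_class = unname(classes[cl]),
      n_valid = nrow(dec), n_timeout = sum(tr$choice == "timeout"),
      rejection_rate = if (nrow(dec) == 0) NA_real_
        else length(rej) / nrow(dec),
      mean_rt_accept = if (length(acc) == 0) NA_real_ else mean(acc),
      mean_rt_reject = if (length(rej) == 0) NA_real_ else mean(rej),
      stringsAsFactors = FALSE)
  }))
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("Group behavior by condition\n")
  print(transform(x$by_condition, rejection_rate = round(rejection_rate, 3),
                  mean_rt_accept = round(mean_rt_accept, 3),
                  mean_rt_reject = round(mean_rt_reject, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Normalized response time
#'
#' Centers each participant's response times on their own mean response time
#' in the equal-split (1/1) condition, removing between-participant speed
#' differences. Timeout trials keep a missing normalized value.
#'
#' @param trials A trial data.frame.
#' @return The table with an added `rt_norm_s` column.
#' @export
normalized_rt <- function(trials) {
  trials <- validate_trials(trials)
  ids <- unique(trials$participant_id)
  trials$rt_norm_s <- NA_real_
  for (id in ids) {
    sel <- trials$participant_id == id
    ref <- trials$rt_s[sel & trials$condition_label == "1/1" &
                         trials$choice != "timeout"]
    if (length(ref) == 0) {
      stop("participant ", id,
           " has no decided 1/1-condition trial to normalize against")
    }
    trials$rt_norm_s[sel] <- trials$rt_s[sel] - mean(ref)
  }
  trials
}

#' Pearson correlations with Holm-Bonferroni correction
#'
#' Computes Pearson's r with a two-sided t-test p-value for each named
#' variable pair and applies the Holm step-down adjustment across the
#' family. Pairs with fewer than 3 complete observations or zero variance
#' are flagged undefined and excluded from the family with a warning.
#'
#' @param pairs A named list; each element is a list (or data.frame) with
#'   numeric elements `x` and `y`.
#' @return Object of class `correlation_report`: data.frame with columns
#'   `pair`, `n`, `r`, `p_value`, `p_holm`, `defined`.
#' @examples
#' pearson_holm(list(a = list(x = 1:10, y = (1:10) + rnorm(10)),
#'                   b = list(x = 1:10, y = rnorm(10))))
#' @export
pearson_holm <- function(pairs) {
  stopifnot(is.list(pairs), !is.null(names(pairs)))
  rows <- lapply(names(pairs), function(nm) {
    x <- pairs[[nm]]$x
    y <- pairs[[nm]]$y
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]
    y <- y[keep]
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
      return(data.frame(pair = nm, n = length(x), r = NA_real_,
                        p_value = NA_real_, defined = FALSE))
    }
    ct <- cor.test(x, y)
    data.frame(pair = nm, n = length(x), r = unname(ct$estimate),
               p_value = ct$p.value, defined = TRUE)
  })
  report <- do.call(rbind, rows)
  if (any(!report$defined)) {
    warning("undefined correlation(s) excluded from the Holm family: ",
            paste(report$pair[!report$defined], collapse = ", "))
  }
  report$p_holm <- NA_real_
  report$p_holm[report$defined] <- p.adjust(report$p_value[report$defined],
                                            method = "holm")
  class(report) <- c("correlation_report", "data.frame")
  report
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Pearson correlations (Holm-adjusted)\n")
  df <- as.data.frame(x)
  df$r <- round(df$r, 3)
  df$p_value <- signif(df$p_value, 3)
  df$p_holm <- signif(df$p_holm, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Drift-parameter vs behavior correlation family
#'
#' The canonical panel family relating individual drift coefficients to
#' individual behavior, Holm-corrected as one family: `beta(DI)` against the
#' rejection rate and against accept/reject response times in DI conditions;
#' `beta(SR)` against the rejection rate and accept response time in unfair
#' (non-1/1) conditions; `beta(AI)` against the rejection rate in AI
#' conditions. Participants whose relevant cell is undefined (e.g. no
#' rejections, hence no reject-RT) are dropped pairwise.
#'
#' @param estimates A data.frame with one row per participant: columns
#'   `participant_id`, `beta_SR`, `beta_DI`, `beta_AI` (e.g. posterior
#'   means).
#' @param behavior A `behavior_summary` (or its `by_participant` data.frame)
#'   computed on the same participants.
#' @return A `correlation_report` over the six panels.
#' @export
drift_behavior_correlations <- function(estimates, behavior) {
  if (inherits(behavior, "behavior_summary")) {
    behavior <- behavior$by_participant
  }
  ids <- estimates$participant_id
  if (is.null(ids)) stop("`estimates` needs a participant_id column")
  if (!setequal(ids, unique(behavior$participant_id))) {
    stop("participant sets of `estimates` and `behavior` do not match")
  }
  if (length(ids) < 3) {
    stop("need at least 3 participants for the correlation family")
  }
  cell <- function(class_sel, col) {
    vapply(ids, function(id) {
      b <- behavior[behavior$participant_id == id &
                      behavior$condition_class %in% class_sel, ]
      w <- b$n_valid
      v <- b[[col]]
      keep <- !is.na(v) & w > 0
      if (!any(keep)) return(NA_real_)
      sum(v[keep] * w[keep]) / sum(w[keep])
    }, numeric(1))
  }
  di_rej <- cell("di", "rejection_rate")
  di_acc_rt <- cell("di", "mean_rt_accept")
  di_rej_rt <- cell("di", "mean_rt_reject")
  unfair_rej <- cell(c("di", "ai"), "rejection_rate")
  unfair_acc_rt <- cell(c("di", "ai"), "mean_rt_accept")
  ai_rej <- cell("ai", "rejection_rate")
  pearson_holm(list(
    beta_DI_vs_rejection_DI = list(x = estimates$beta_DI, y = di_rej),
    beta_DI_vs_accept_rt_DI = list(x = estimates$beta_DI, y = di_acc_rt),
    beta_DI_vs_reject_rt_DI = list(x = estimates$beta_DI, y = di_rej_rt),
    beta_SR_vs_rejection_unfair = list(x = estimates$beta_SR,
                                       y = unfair_rej),
    beta_SR_vs_accept_rt_unfair = list(x = estimates$beta_SR,
                                       y = unfair_acc_rt),
    beta_AI_vs_rejection_AI = list(x = estimates$beta_AI, y = ai_rej)
  ))
}
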
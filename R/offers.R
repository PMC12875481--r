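#' The seven base offers of the ultimatum-game task
#'
#' The responder (self) / proposer (other) base splits of a fixed ¥500 pie,
#' labelled by their self:other reward ratio. On each trial the displayed
#' rewards are the base rewards plus independent jitter of up to ¥25.
#'
#' @return A data.frame with columns `condition_label`, `sr_yen` (responder
#'   reward) and `or_yen` (proposer reward), one row per base condition in
#'   decreasing self-reward order.
#' @examples
#' base_offers()
#' @export
base_offers <- function() {
  data.frame(
    condition_label = c("7/3", "3/2", "1/1", "2/3", "3/7", "1/4", "1/9"),
    sr_yen = c(350L, 300L, 250L, 200L, 150L, 100L, 50L),
    or_yen = c(150L, 200L, 250L, 300L, 350L, 400L, 450L),
    stringsAsFactors = FALSE
  )
}

#' Condition labels in fairness order
#'
#' Conditions with self:other ratio below 1 carry disadvantageous inequity
#' (DI), the 1/1 split is fair, and ratios above 1 carry advantageous
#' inequity (AI).
#'
#' @return Named character vector mapping each condition label to one of
#'   `"di"`, `"fair"`, `"ai"`.
#' @export
condition_classes <- function() {
  c("7/3" = "ai", "3/2" = "ai", "1/1" = "fair",
    "2/3" = "di", "3/7" = "di", "1/4" = "di", "1/9" = "di")
}

#' Generate one 56-trial offer set
#'
#' Builds the task's offer sequence: 8 trials of each of the 7 base offers,
#' each displayed reward independently perturbed by a uniform draw from the
#' symmetric jitter grid `{-jitter_max_yen, ..., +jitter_max_yen}` with step
#' `jitter_step_yen`, and the trial order shuffled. Fully deterministic given
#' the seed.
#'
#' @param seed Integer seed controlling jitter and trial order.
#' @param jitter_step_yen Grid step of the jitter in yen; must divide
#'   `jitter_max_yen`. Default 5.
#' @param jitter_max_yen Maximum absolute jitter in yen (default 25). Set to
#'   0 for the degenerate zero-jitter design that repeats the base pairs
#'   exactly.
#' @param trials_per_condition Trials per base offer (default 8, giving 56).
#' @return A data.frame of offers with columns `condition_label`, `sr_yen`,
#'   `or_yen`.
#' @examples
#' offers <- generate_offer_set(seed = 1)
#' table(offers$condition_label)
#' @export
generate_offer_set <- function(seed, jitter_step_yen = 5, jitter_max_yen = 25,
                               trials_per_condition = 8) {
  stopifnot(length(seed) == 1, is.finite(seed), seed >= 0)
  if (jitter_max_yen > 0) {
    if (jitter_step_yen <= 0 || jitter_max_yen %% jitter_step_yen != 0) {
      stop("`jitter_step_yen` must be a positive divisor of `jitter_max_yen`")
    }
  }
  base <- base_offers()
  offers <- base[rep(seq_len(nrow(base)), each = trials_per_condition), ]
  rownames(offers) <- NULL
  withr::with_seed(as.integer(seed), {
    n <- nrow(offers)
    if (jitter_max_yen > 0) {
      grid <- seq(-jitter_max_yen, jitter_max_yen, by = jitter_step_yen)
      offers$sr_yen <- offers$sr_yen + sample(grid, n, replace = TRUE)
      offers$or_yen <- offers$or_yen + sample(grid, n, replace = TRUE)
    }
    offers <- offers[sample.int(n), ]
  })
  rownames(offers) <- NULL
  offers
}

#' Inequity regressors of an offer
#'
#' Scales the displayed rewards into model units and derives the inequity
#' terms: disadvantageous inequity `di = max(or - sr, 0)` and advantageous
#' inequity `ai = max(sr - or, 0)`, so that exactly one of the two is nonzero
#' on any unequal offer.
#'
#' @param offers A data.frame with columns `sr_yen` and `or_yen` (an offer
#'   set or a trial table).
#' @param scale_yen Yen per model unit; default 100, placing self-reward in
#'   roughly `[0.25, 3.75]` so drift coefficients live comfortably inside
#'   their `(-3, 3)` prior support.
#' @return A data.frame with columns `sr`, `or_`, `di`, `ai` and attribute
#'   `scale_yen`.
#' @examples
#' compute_features(data.frame(sr_yen = 50, or_yen = 450))
#' @export
compute_features <- function(offers, scale_yen = 100) {
  stopifnot(is.data.frame(offers), scale_yen > 0)
  if (!all(c("sr_yen", "or_yen") %in% names(offers))) {
    stop("`offers` must have columns sr_yen and or_yen")
  }
  if (any(offers$sr_yen < 0 | offers$or_yen < 0, na.rm = TRUE)) {
    stop("invalid offer: negative yen amounts")
  }
  sr <- offers$sr_yen / scale_yen
  or_ <- offers$or_yen / scale_yen
  out <- data.frame(
    sr = sr, or_ = or_,
    di = pmax(or_ - sr, 0),
    ai = pmax(sr - or_, 0)
  )
  attr(out, "scale_yen") <- scale_yen
  out
}

# Assign the nearest base condition label to displayed rewards. Base pairs
# are >= 50 yen apart in self-reward while jitter is at most 25, so the
# assignment is unambiguous for task-conforming offers.
infer_condition_label <- function(sr_yen, or_yen) {
  base <- base_offers()
  idx <- vapply(seq_along(sr_yen), function(i) {
    d <- abs(base$sr_yen - sr_yen[i]) + abs(base$or_yen - or_yen[i])
    which.min(d)
  }, integer(1))
  base$condition_label[idx]
}
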
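#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale reduction computed after splitting each chain in half
#' (guarding against within-chain trends), together with an effective sample
#' size from Geyer's initial positive sequence of autocorrelations. Values of
#' R-hat at or below 1.1 are the conventional convergence criterion; the
#' report flags parameters above that threshold. Chains that are all constant
#' and equal report exactly 1.
#'
#' @param fit A `ddm_fit`, or a numeric array (chains x iterations x
#'   parameters).
#' @param threshold Flagging threshold (default 1.1).
#' @return Object of class `convergence_report`: list with `rhat`,
#'   `effective_sample_size`, `flagged`, `threshold`.
#' @export
gelman_rubin <- function(fit, threshold = 1.1) {
  draws <- if (inherits(fit, "ddm_fit")) fit$draws else fit
  stopifnot(is.array(draws), length(dim(draws)) == 3)
  m <- dim(draws)[1]
  n <- dim(draws)[2]
  if (m < 2) stop("at least 2 chains are required for the diagnostic")
  if (n < 10) stop("at least 10 retained iterations per chain are required")
  pars <- dimnames(draws)[[3]]
  if (is.null(pars)) pars <- paste0("par", seq_len(dim(draws)[3]))
  rhat <- vapply(seq_len(dim(draws)[3]), function(j) {
    split_rhat(draws[, , j, drop = FALSE])
  }, numeric(1))
  ess <- vapply(seq_len(dim(draws)[3]), function(j) {
    ess_geyer(draws[, , j, drop = FALSE])
  }, numeric(1))
  names(rhat) <- names(ess) <- pars
  structure(list(rhat = rhat, effective_sample_size = ess,
                 flagged = pars[rhat > threshold], threshold = threshold),
            class = "convergence_report")
}

# Split-chain potential scale reduction for one parameter.
# x: chains x iterations x 1 array.
split_rhat <- function(x) {
  m <- dim(x)[1]
  n <- dim(x)[2]
  half <- n %/% 2
  # split each chain into first/second halves
  chains <- vector("list", 2 * m)
  for (c in seq_len(m)) {
    chains[[2 * c - 1]] <- x[c, seq_len(half), 1]
    chains[[2 * c]] <- x[c, half + seq_len(half), 1]
  }
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  B <- half * var(means)
  if (W == 0) {
    # degenerate all-constant chains: converged by definition if equal
    return(if (var(means) == 0) 1 else Inf)
  }
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Effective sample size via Geyer's initial positive sequence, computed on
# chain-centered draws pooled across chains.
ess_geyer <- function(x) {
  m <- dim(x)[1]
  n <- dim(x)[2]
  centered <- lapply(seq_len(m), function(c) x[c, , 1] - mean(x[c, , 1]))
  if (all(vapply(centered, function(v) all(v == 0), logical(1)))) {
    return(m * n)
  }
  max_lag <- min(n - 1, 200)
  acf_mean <- vapply(0:max_lag, function(l) {
    mean(vapply(centered, function(v) {
      sum(v[seq_len(n - l)] * v[seq_len(n - l) + l]) / n
    }, numeric(1)))
  }, numeric(1))
  acf_mean <- acf_mean / acf_mean[1]
  # sum consecutive lag pairs while positive
  s <- 0
  l <- 1
  while (l + 1 <= length(acf_mean)) {
    pair <- acf_mean[l + 1] + (if (l + 2 <= length(acf_mean))
      acf_mean[l + 2] else 0)
    if (pair < 0) break
    s <- s + pair
    l <- l + 2
  }
  max(m * n / (1 + 2 * s), 1)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence report (split-chain R-hat)\n")
  print(round(rbind(rhat = x$rhat, ess = x$effective_sample_size), 3))
  if (length(x$flagged) > 0) {
    cat("FLAGGED (R-hat > ", x$threshold, "): ",
        paste(x$flagged, collapse = ", "), "\n", sep = "")
  } else {
    cat("All parameters below the", x$threshold, "threshold\n")
  }
  invisible(x)
}
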
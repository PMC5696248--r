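#' @noRd
.assert_fraction <- function(x, name, allow_na = FALSE) {
  if (allow_na && all(is.na(x))) return(invisible(x))
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a fraction in [0, 1].", name))
  }
  invisible(x)
}

#' @noRd
.assert_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(!is.finite(x) | x <= 0) else any(!is.finite(x) | x < 0)
  if (!is.numeric(x) || bad) {
    abort(sprintf("`%s` must be %s.", name,
                  if (strict) "a positive number" else "a non-negative number"))
  }
  invisible(x)
}

# Median of |exp(sigma * Z) - 1| for standard normal Z: the MAD/median ratio
# of a log-normal distribution. Always < 1, which is why heavy-tailed
# empirical MAD/median ratios need the quantile-based fallback below.
.lnorm_mad_ratio <- function(sigma) {
  if (sigma <= 0) return(0)
  f <- function(t) {
    upper <- pnorm(log1p(t) / sigma)
    lower <- if (t < 1) pnorm(log(1 - t) / sigma) else 0
    upper - lower - 0.5
  }
  uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-10)$root
}

#' Log-scale spread of a log-normal from a robust location/spread pair
#'
#' Given a target median and median absolute deviation (both on the raw
#' measurement scale), returns the `sdlog` of a log-normal with that median
#' whose spread approximates the target. When `mad / median < 0.95` the MAD
#' is matched exactly (numerically inverting the log-normal MAD/median
#' ratio). A log-normal cannot attain MAD/median >= 1, so heavier-tailed
#' targets fall back to matching the 90th percentile to
#' `median * (1 + mad / median)`.
#'
#' @param median Target median, positive.
#' @param mad Target median absolute deviation, positive.
#' @return A single positive `sdlog` value.
#' @export
#' @examples
#' lnorm_sdlog_from_mad(7.4, 3.6)
lnorm_sdlog_from_mad <- function(median, mad) {
  .assert_positive(median, "median")
  .assert_positive(mad, "mad")
  ratio <- mad / median
  if (ratio < 0.95) {
    # sdlog <= 3 always suffices here: the log-normal MAD/median ratio
    # reaches 0.95 well before sdlog 3, and larger ratios take the
    # quantile branch
    uniroot(function(s) .lnorm_mad_ratio(s) - ratio, c(1e-6, 3),
            tol = 1e-9)$root
  } else {
    log(1 + ratio) / qnorm(0.9)
  }
}

#' Log-scale mean shift that yields a target two-class AUC
#'
#' For two log-normal populations with common `sdlog`, the AUC of the raw
#' level as a classifier is `pnorm(delta / (sdlog * sqrt(2)))` where `delta`
#' is the difference of the log-scale means. This inverts that relation;
#' it is how the synthetic generator turns a target single-marker AUC into
#' an effect size.
#'
#' @param auc Target AUC in (0.5, 1).
#' @param sdlog Common log-scale standard deviation.
#' @return The log-scale location shift (positive).
#' @export
effect_for_auc <- function(auc, sdlog = 0.5) {
  if (any(auc <= 0) || any(auc >= 1)) abort("`auc` must lie in (0, 1).")
  .assert_positive(sdlog, "sdlog")
  sqrt(2) * sdlog * qnorm(auc)
}

# Blocked randomization: deal each group's (shuffled) samples round-robin
# across batches so per-batch group composition deviates from the global
# composition by at most one sample per group.
.blocked_batches <- function(group, batch_size) {
  n <- length(group)
  n_batch <- max(1L, ceiling(n / batch_size))
  batch <- integer(n)
  for (g in unique(group)) {
    idx <- sample(which(group == g))
    batch[idx] <- rep_len(seq_len(n_batch), length(idx))
  }
  # rebalance start offsets so batch 1 is not systematically largest
  sprintf("B%02d", batch)
}

#' @noRd
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}
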
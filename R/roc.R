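#' @noRd
.check_two_class <- function(labels) {
  if (!is.logical(labels)) abort("`labels` must be logical (TRUE = case).")
  if (!any(labels) || all(labels)) {
    abort("Both cases and controls are required.")
  }
  invisible(labels)
}

#' Area under the empirical ROC curve
#'
#' The Mann-Whitney formulation: the probability that a random case scores
#' above a random control, counting ties as one half. Equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores, higher meaning more case-like.
#' @param labels Logical, `TRUE` for cases.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))  # 1
roc_auc <- function(scores, labels) {
  .check_two_class(labels)
  if (length(scores) != length(labels)) abort("Length mismatch.")
  ok <- is.finite(scores)
  scores <- scores[ok]; labels <- labels[ok]
  .check_two_class(labels)
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# placement values: for each case, the fraction of controls it beats
# (ties 1/2), and symmetrically for controls. The structural components
# of the DeLong covariance estimator.
.placements <- function(scores, labels) {
  cases <- scores[labels]; controls <- scores[!labels]
  m <- length(cases); n <- length(controls)
  # rank trick: midranks of the pooled sample give both placement sets
  all_r <- rank(c(cases, controls))
  case_r <- rank(cases); ctrl_r <- rank(controls)
  v10 <- (all_r[seq_len(m)] - case_r) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - ctrl_r) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two paired AUCs
#'
#' Nonparametric comparison of the AUCs of two classifiers scored on the
#' same samples, using the structural-components (placement-value)
#' estimator of the paired AUC covariance matrix and a two-sided z test of
#' equal AUC. Identical scores (zero estimated variance of the difference)
#' return p = 1 with a degenerate-variance flag.
#'
#' @param scores_a,scores_b Score vectors of the two classifiers on the
#'   same samples, case-oriented.
#' @param labels Logical, `TRUE` for cases.
#' @return An object of class `delong_comparison`: AUCs, variance of the
#'   difference, `z`, `p_value`, `degenerate` flag, and the AUC difference
#'   `auc_a - auc_b`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  .check_two_class(labels)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    abort("Score vectors must cover the same samples as `labels`.")
  }
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  degenerate <- !is.finite(var_diff) || var_diff <= .Machine$double.eps
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = pa$auc - pb$auc,
         var_diff = var_diff, z = z, p_value = p,
         degenerate = degenerate, n_cases = m, n_controls = n),
    class = "delong_comparison"
  )
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat("DeLong paired AUC comparison\n")
  cat(sprintf("  AUC A = %.4f, AUC B = %.4f, diff = %+.4f\n",
              x$auc_a, x$auc_b, x$auc_diff))
  cat(sprintf("  z = %.3f, two-sided p = %.4g%s\n", x$z, x$p_value,
              if (x$degenerate) " (degenerate variance)" else ""))
  invisible(x)
}

#' @export
tidy.delong_comparison <- function(x, ...) {
  tibble(auc_a = x$auc_a, auc_b = x$auc_b, auc_diff = x$auc_diff,
         statistic = x$z, p.value = x$p_value,
         degenerate = x$degenerate)
}

#' Decision cutoff at a fixed training specificity
#'
#' Finds the smallest decision threshold whose training-set specificity
#' (fraction of controls scoring strictly below it, under the
#' score-at-least-cutoff positive rule) meets the target. The cutoff is
#' meant to be frozen and transferred to test cohorts; with tied or coarse
#' scores the achieved specificity can exceed the target.
#'
#' @param scores Case-oriented scores on the training cohort.
#' @param labels Logical, `TRUE` for cases.
#' @param spec_target Target specificity in (0, 1).
#' @return A list: `cutoff`, `specificity` (achieved, training),
#'   `sensitivity` (training).
#' @export
#' @examples
#' sensitivity_at_specificity(1:20, rep(c(FALSE, TRUE), each = 10), 0.9)
sensitivity_at_specificity <- function(scores, labels, spec_target = 0.9) {
  if (spec_target <= 0 || spec_target >= 1) {
    if (spec_target != 1) abort("`spec_target` must lie in (0, 1].")
  }
  if (!any(!labels)) abort("Controls are required to set a cutoff.")
  v <- sort(unique(scores[is.finite(scores)]))
  # candidate thresholds between observed values (and beyond the extremes)
  cand <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + 1)
  controls <- sort(scores[!labels])
  # candidates are midpoints strictly between observed values (or beyond
  # the extremes), so they never tie with a control score and
  # findInterval counts exactly the controls below each candidate
  spec <- findInterval(cand, controls) / length(controls)
  ok <- which(spec >= spec_target)
  if (length(ok) == 0) ok <- length(cand)
  cutoff <- cand[min(ok)]
  res <- apply_cutoff(scores, labels, cutoff)
  list(cutoff = cutoff, specificity = res$specificity,
       sensitivity = res$sensitivity)
}

#' Apply a frozen decision cutoff
#'
#' Predictions are positive when the case-oriented score is at least the
#' cutoff; sensitivity and specificity are computed on the given labels.
#'
#' @param scores Case-oriented scores.
#' @param labels Logical, `TRUE` for cases.
#' @param cutoff Decision threshold frozen on a training cohort.
#' @return A list: `sensitivity`, `specificity`, `predictions` (logical).
#' @export
apply_cutoff <- function(scores, labels, cutoff) {
  pred <- scores >= cutoff
  sens <- if (any(labels)) mean(pred[labels], na.rm = TRUE) else NA_real_
  spec <- if (any(!labels)) mean(!pred[!labels], na.rm = TRUE) else NA_real_
  list(sensitivity = sens, specificity = spec, predictions = pred)
}

#' McNemar's test on paired predictions
#'
#' Compares two classifiers' binary predictions on the same samples via
#' their discordant counts: `b` = A correct and B wrong, `c` = A wrong and
#' B correct. Uses the exact two-sided binomial test when `b + c < 25` and
#' the continuity-corrected chi-squared approximation otherwise. With
#' `scope = "cases"` only case samples enter (a paired comparison of
#' sensitivities at matched specificity); `scope = "all"` tests overall
#' diagnostic homogeneity.
#'
#' @param pred_a,pred_b Logical predicted-positive vectors.
#' @param labels Logical, `TRUE` for cases.
#' @param scope `"cases"` or `"all"`.
#' @return An object of class `mcnemar_comparison`: `b`, `c`, `p_value`,
#'   `method`, `no_discordance` flag.
#' @export
mcnemar_test <- function(pred_a, pred_b, labels, scope = c("cases", "all")) {
  scope <- match.arg(scope)
  if (length(pred_a) != length(labels) || length(pred_b) != length(labels)) {
    abort("Prediction vectors must cover the same samples as `labels`.")
  }
  keep <- if (scope == "cases") labels else rep(TRUE, length(labels))
  keep <- keep & !is.na(pred_a) & !is.na(pred_b)
  correct_a <- pred_a[keep] == labels[keep]
  correct_b <- pred_b[keep] == labels[keep]
  b <- sum(correct_a & !correct_b)
  c_ <- sum(!correct_a & correct_b)
  nd <- b + c_
  if (nd == 0) {
    p <- 1; method <- "exact"
  } else if (nd < 25) {
    p <- min(1, 2 * pbinom(min(b, c_), nd, 0.5))
    method <- "exact"
  } else {
    stat <- (abs(b - c_) - 1)^2 / nd
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chisq"
  }
  structure(
    list(b = b, c = c_, p_value = p, method = method,
         no_discordance = nd == 0, scope = scope),
    class = "mcnemar_comparison"
  )
}

#' @export
print.mcnemar_comparison <- function(x, ...) {
  cat(sprintf("McNemar paired test (%s, scope=%s): b = %d, c = %d, p = %.4g\n",
              x$method, x$scope, x$b, x$c, x$p_value))
  invisible(x)
}

#' @export
tidy.mcnemar_comparison <- function(x, ...) {
  tibble(b = x$b, c = x$c, p.value = x$p_value, method = x$method,
         scope = x$scope)
}

#' Positive predictive value under a population prevalence
#'
#' `PPV = (Se * P) / (Se * P + (1 - Sp) * (1 - P))` with prevalence `P`.
#' The default prevalence, 12.9 per 100,000, is the pancreatic-cancer
#' prevalence used throughout the package's validation reports. A zero
#' denominator is defined as PPV 0 (with a warning).
#'
#' @param sensitivity,specificity,prevalence Fractions in \[0, 1\].
#' @return The PPV as a fraction.
#' @export
#' @examples
#' ppv(0.825, 0.944)
ppv <- function(sensitivity, specificity, prevalence = 12.9e-5) {
  .assert_fraction(sensitivity, "sensitivity")
  .assert_fraction(specificity, "specificity")
  .assert_fraction(prevalence, "prevalence")
  num <- sensitivity * prevalence
  den <- num + (1 - specificity) * (1 - prevalence)
  out <- ifelse(den == 0, 0, num / den)
  if (any(den == 0)) warn("Zero PPV denominator; PPV defined as 0.")
  out
}

#' Empirical ROC curve coordinates
#'
#' @param scores Case-oriented scores.
#' @param labels Logical, `TRUE` for cases.
#' @return A tibble `fpr`, `tpr`, `cutoff`, suitable for plotting.
#' @export
roc_curve <- function(scores, labels) {
  .check_two_class(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(!l)
  keep <- !duplicated(s, fromLast = TRUE)
  tibble(
    fpr = c(0, fp[keep] / sum(!labels)),
    tpr = c(0, tp[keep] / sum(labels)),
    cutoff = c(Inf, s[keep])
  )
}
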
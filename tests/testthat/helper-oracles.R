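# Independent reference implementations used to validate the package's
# statistics. These are deliberately naive (double loops, exhaustive
# enumeration) so they cannot share bugs with the vectorized versions.

# AUC by exhaustive case-control pair counting (ties count one half).
oracle_auc <- function(scores, labels) {
  cases <- scores[labels]
  controls <- scores[!labels]
  total <- 0
  for (x in cases) {
    for (y in controls) {
      total <- total + (x > y) + 0.5 * (x == y)
    }
  }
  total / (length(cases) * length(controls))
}

# DeLong structural components and variance of the AUC difference,
# computed with explicit double loops (no rank tricks).
oracle_delong <- function(sa, sb, labels) {
  place <- function(s) {
    cases <- s[labels]
    controls <- s[!labels]
    m <- length(cases)
    n <- length(controls)
    v10 <- vapply(cases, function(x) {
      mean((x > controls) + 0.5 * (x == controls))
    }, numeric(1))
    v01 <- vapply(controls, function(y) {
      mean((cases > y) + 0.5 * (cases == y))
    }, numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- place(sa)
  pb <- place(sb)
  m <- sum(labels)
  n <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  z <- (pa$auc - pb$auc) / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Exact two-sided McNemar p by brute-force Binomial(b+c, 1/2) pmf sums.
oracle_mcnemar_exact <- function(b, c_) {
  nd <- b + c_
  if (nd == 0) return(1)
  k <- min(b, c_)
  tail <- sum(vapply(0:k, function(i) choose(nd, i) * 0.5^nd, numeric(1)))
  min(1, 2 * tail)
}

# Cutoff at a target specificity by exhaustive threshold scan over a
# dense candidate grid (every midpoint and both extremes), returning the
# smallest candidate meeting the target.
oracle_cutoff <- function(scores, labels, target) {
  v <- sort(unique(scores))
  cand <- sort(c(v[1] - 1, (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1))
  controls <- scores[!labels]
  for (ct in cand) {
    if (mean(controls < ct) >= target) return(ct)
  }
  cand[length(cand)]
}

# Synthetic marker table used by the panel-recovery and no-leakage tests:
# an anchor-like marker with a non-expressor mixture plus two informative
# markers and null decoys, all independent log-normals.
make_recovery_cohort <- function(seed, n_cases = 321, n_controls = 363,
                                 auc_marker = 0.70, auc_anchor = 0.82,
                                 nonexpressor_fraction = 0.125,
                                 n_decoys = 20, informative = TRUE) {
  withr::with_seed(seed, {
    n <- n_cases + n_controls
    is_case <- rep(c(TRUE, FALSE), c(n_cases, n_controls))
    auc_expressor <- (auc_anchor - nonexpressor_fraction * 0.5) /
      (1 - nonexpressor_fraction)
    d_anchor <- effect_for_auc(auc_expressor, 0.8)
    d_marker <- if (informative) effect_for_auc(auc_marker, 0.5) else 0
    expressor <- !is_case | (runif(n) > nonexpressor_fraction)
    dat <- tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      is_case = is_case,
      ca199 = rlnorm(n, log(7.4) + d_anchor * (is_case & expressor), 0.8),
      LRG1 = rlnorm(n, d_marker * is_case, 0.5),
      TTR = rlnorm(n, -d_marker * is_case, 0.5)
    )
    for (j in seq_len(n_decoys)) {
      dat[[sprintf("DEC%02d", j)]] <- rlnorm(n, 0, 0.5)
    }
    dat
  })
}

# Cohort for the scenario-pattern test: CA19-9 carries no signal below
# 37 U/mL by construction (normal-range cases draw from the control
# distribution; expressor cases sit at median 300 with sdlog 0.8, so
# essentially none fall below 37). The normal-range case fraction 0.36
# puts the overall anchor AUC at ~0.82, and the AUC-0.75 markers put the
# marker-only low-CA19-9 panel AUC at ~0.83.
make_scenario_cohort <- function(seed, n_pdac = 1000, n_nl = 800,
                                 normal_range_fraction = 0.36,
                                 marker_auc = 0.75) {
  withr::with_seed(seed, {
    n <- n_pdac + n_nl
    is_case <- rep(c(TRUE, FALSE), c(n_pdac, n_nl))
    low_signal <- is_case & (runif(n) < normal_range_fraction)
    meanlog <- ifelse(is_case & !low_signal, log(300), log(7.4))
    d_marker <- effect_for_auc(marker_auc, 0.5)
    tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      group = ifelse(is_case, "PDAC", "NL"),
      stage = ifelse(is_case, "II", NA_character_),
      is_case = is_case,
      ca199 = rlnorm(n, meanlog, 0.8),
      LRG1 = rlnorm(n, d_marker * is_case, 0.5),
      TTR = rlnorm(n, -d_marker * is_case, 0.5)
    )
  })
}
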
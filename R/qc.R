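#' Verification-stage QC configuration
#'
#' Thresholds for the marker verification filters. Defaults: replicate CV
#' cutoff 10%, relative-level reference range the open interval (0.1, 10),
#' single-marker AUC screen at 0.60, interference flagging at a one-sided
#' discordance p below 0.05 or a ratio CV above 0.20 with a peptide failing
#' when its signature transition is flagged in more than half the samples,
#' and a BH-adjusted alpha of 0.05 for the center/batch confounder screen.
#'
#' @param cv_threshold Replicate-CV cutoff (fraction).
#' @param level_range Length-2 numeric, open reference interval for the
#'   median relative level.
#' @param audit_pvalue_threshold One-sided paired-t p-value threshold for
#'   light-vs-heavy relative-intensity discordance.
#' @param audit_cv_threshold Replicate CV threshold of the light:heavy
#'   ratio used by the interference flag.
#' @param audit_sample_fraction Fraction of samples in which a transition
#'   must be flagged for the pair (and the peptide, when it is the
#'   signature transition) to fail.
#' @param confounder_alpha BH-adjusted significance level of the
#'   center/batch Kruskal-Wallis screen.
#' @param auc_screen_threshold Single-marker oriented-AUC threshold
#'   (strictly greater passes).
#' @param gate_comparison Which pairwise comparison gates the AUC screen:
#'   `"NL_vs_PDAC"` or `"PB_vs_PDAC"`.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(cv_threshold = 0.10,
                      level_range = c(0.1, 10),
                      audit_pvalue_threshold = 0.05,
                      audit_cv_threshold = 0.20,
                      audit_sample_fraction = 0.5,
                      confounder_alpha = 0.05,
                      auc_screen_threshold = 0.60,
                      gate_comparison = c("NL_vs_PDAC", "PB_vs_PDAC")) {
  .assert_fraction(cv_threshold, "cv_threshold")
  .assert_fraction(audit_pvalue_threshold, "audit_pvalue_threshold")
  .assert_positive(audit_cv_threshold, "audit_cv_threshold")
  .assert_fraction(audit_sample_fraction, "audit_sample_fraction")
  .assert_fraction(confounder_alpha, "confounder_alpha")
  if (auc_screen_threshold < 0.5 || auc_screen_threshold > 1) {
    abort("`auc_screen_threshold` must lie in [0.5, 1].")
  }
  if (length(level_range) != 2 || level_range[1] >= level_range[2]) {
    abort("`level_range` must be c(lower, upper), lower < upper.")
  }
  structure(
    list(cv_threshold = cv_threshold, level_range = level_range,
         audit_pvalue_threshold = audit_pvalue_threshold,
         audit_cv_threshold = audit_cv_threshold,
         audit_sample_fraction = audit_sample_fraction,
         confounder_alpha = confounder_alpha,
         auc_screen_threshold = auc_screen_threshold,
         gate_comparison = match.arg(gate_comparison)),
    class = "qc_config"
  )
}

#' Replicate-CV stability filter
#'
#' A peptide fails when its summary replicate CV — the median across
#' samples of the per-sample triplicate CV — exceeds the threshold.
#' Peptides with no computable CV are reported unevaluable, not failed.
#'
#' @param quant Output of [quantify_transitions()].
#' @param threshold CV cutoff (default 0.10).
#' @return A tibble per peptide: `peptide`, `protein`, `median_cv`,
#'   `status` (`"pass"`, `"fail"`, `"unevaluable"`), `rule = "cv"`.
#' @export
cv_filter <- function(quant, threshold = 0.10) {
  quant %>%
    group_by(.data$protein, .data$peptide) %>%
    summarise(median_cv = median(.data$replicate_cv, na.rm = TRUE),
              .groups = "drop") %>%
    mutate(
      status = dplyr::case_when(
        !is.finite(.data$median_cv) ~ "unevaluable",
        .data$median_cv > .env$threshold ~ "fail",
        TRUE ~ "pass"),
      rule = "cv"
    )
}

#' Relative-level reference-range filter
#'
#' A peptide fails when its median relative level across samples falls
#' outside the open reference interval (boundary values fail).
#'
#' @param quant Output of [quantify_transitions()].
#' @param level_range Open interval, default `c(0.1, 10)`.
#' @return A tibble per peptide with `median_level`, `status`,
#'   `rule = "range"`.
#' @export
range_filter <- function(quant, level_range = c(0.1, 10)) {
  quant %>%
    group_by(.data$protein, .data$peptide) %>%
    summarise(median_level = median(
      .data$relative_level[!.data$missing_quant], na.rm = TRUE),
      .groups = "drop") %>%
    mutate(
      status = dplyr::case_when(
        !is.finite(.data$median_level) ~ "unevaluable",
        .data$median_level > .env$level_range[1] &
          .data$median_level < .env$level_range[2] ~ "pass",
        TRUE ~ "fail"),
      rule = "range"
    )
}

# one-sided paired comparison of light vs heavy fractional contributions
# across replicates; returns p (NA when not evaluable)
.discordance_p <- function(light_frac, heavy_frac) {
  d <- light_frac - heavy_frac
  d <- d[is.finite(d)]
  if (length(d) < 2) return(NA_real_)
  if (sd(d) == 0) {
    # replicate-identical difference: definite discordance if positive
    return(if (mean(d) > 1e-12) 0 else 1)
  }
  tt <- t.test(d, alternative = "greater")
  unname(tt$p.value)
}

#' Flag interfered transitions (AuDIT-style)
#'
#' Detects transition interference from the discordance between the light
#' (endogenous) and heavy (stable-isotope standard) relative transition
#' intensities, per peptide and sample: each transition's fractional
#' contribution to the summed light area and to the summed heavy area is
#' computed per replicate; a one-sided paired t-test asks whether the
#' light contribution systematically exceeds the heavy one (additive
#' contamination inflates only the light channel), and the replicate CV of
#' the light:heavy ratio is checked against its own threshold. A
#' transition is flagged in a sample when the discordance p-value is below
#' `audit_pvalue_threshold` or the ratio CV exceeds `audit_cv_threshold`;
#' a (peptide, transition) pair is called interfered when flagged in more
#' than `audit_sample_fraction` of samples. Peptides with a single
#' transition are not evaluable (relative contributions are degenerate).
#'
#' @param transitions Transition records (`sample_id`, `replicate`,
#'   `peptide`, `protein`, `transition_id`, `area_light`, `area_heavy`).
#' @param config A [qc_config()].
#' @return A list: `per_sample` (tibble with one row per
#'   peptide-sample-transition: `p_discordance`, `ratio_cv`, `flagged`)
#'   and `per_transition` (tibble per peptide-transition: `flag_rate`,
#'   `interfered`, `evaluable`).
#' @export
audit_flag <- function(transitions, config = qc_config()) {
  df <- transitions %>%
    group_by(.data$peptide, .data$sample_id, .data$replicate) %>%
    mutate(light_frac = .data$area_light / sum(.data$area_light),
           heavy_frac = .data$area_heavy / sum(.data$area_heavy),
           n_transitions = dplyr::n_distinct(.data$transition_id)) %>%
    ungroup() %>%
    mutate(ratio = relative_level(.data$area_light, .data$area_heavy))

  # vectorized one-sided paired t on d = light_frac - heavy_frac
  per_sample <- df %>%
    mutate(d = .data$light_frac - .data$heavy_frac) %>%
    group_by(.data$protein, .data$peptide, .data$sample_id,
             .data$transition_id) %>%
    summarise(
      n_rep = sum(is.finite(.data$ratio)),
      evaluable = .data$n_transitions[1] >= 2 & .data$n_rep >= 2,
      mean_d = mean(.data$d[is.finite(.data$d)]),
      sd_d = sd(.data$d[is.finite(.data$d)]),
      mean_r = mean(.data$ratio[is.finite(.data$ratio)]),
      sd_r = sd(.data$ratio[is.finite(.data$ratio)]),
      .groups = "drop"
    ) %>%
    mutate(
      p_discordance = dplyr::case_when(
        !.data$evaluable ~ NA_real_,
        .data$sd_d == 0 & .data$mean_d > 1e-12 ~ 0,
        .data$sd_d == 0 ~ 1,
        TRUE ~ pt(.data$mean_d / (.data$sd_d / sqrt(.data$n_rep)),
                  df = .data$n_rep - 1, lower.tail = FALSE)),
      ratio_cv = ifelse(.data$evaluable & is.finite(.data$mean_r) &
                          .data$mean_r != 0,
                        .data$sd_r / .data$mean_r, NA_real_)
    ) %>%
    select(-"mean_d", -"sd_d", -"mean_r", -"sd_r") %>%
    mutate(flagged = .data$evaluable &
             ((is.finite(.data$p_discordance) &
                 .data$p_discordance < config$audit_pvalue_threshold) |
                (is.finite(.data$ratio_cv) &
                   .data$ratio_cv > config$audit_cv_threshold)))

  per_transition <- per_sample %>%
    group_by(.data$protein, .data$peptide, .data$transition_id) %>%
    summarise(
      evaluable = any(.data$evaluable),
      flag_rate = ifelse(any(.data$evaluable),
                         mean(.data$flagged[.data$evaluable]), NA_real_),
      .groups = "drop"
    ) %>%
    mutate(interfered = .data$evaluable & !is.na(.data$flag_rate) &
             .data$flag_rate > config$audit_sample_fraction)

  list(per_sample = per_sample, per_transition = per_transition)
}

#' Interference verdict per peptide
#'
#' A peptide fails the interference rule when its signature transition is
#' called interfered by [audit_flag()]; single-transition peptides are
#' unevaluable.
#'
#' @param transitions Transition records.
#' @param quant Output of [quantify_transitions()] (supplies the signature
#'   transition of each peptide).
#' @param config A [qc_config()].
#' @return A tibble per peptide with `status` and `rule = "audit"`.
#' @export
audit_filter <- function(transitions, quant, config = qc_config()) {
  flags <- audit_flag(transitions, config)$per_transition
  sig <- distinct(quant, .data$protein, .data$peptide,
                  .data$signature_transition)
  sig %>%
    left_join(flags, by = c("protein", "peptide",
                            "signature_transition" = "transition_id")) %>%
    mutate(
      status = dplyr::case_when(
        is.na(.data$evaluable) | !.data$evaluable ~ "unevaluable",
        .data$interfered ~ "fail",
        TRUE ~ "pass"),
      rule = "audit"
    ) %>%
    select("protein", "peptide", "flag_rate", "status", "rule")
}

#' Center/batch confounder filter
#'
#' Screens each peptide for association of its relative level with
#' clinical center and with preparation batch, within the control group
#' only (so disease effects cannot masquerade as nuisance effects), using
#' one-way Kruskal-Wallis rank tests and Benjamini-Hochberg correction
#' across peptides per factor. A peptide fails when either adjusted
#' p-value falls below `alpha`. A factor with a single observed level is
#' skipped with a warning.
#'
#' @param quant Output of [quantify_transitions()].
#' @param meta Sample metadata (needs `sample_id`, `group`, `center`,
#'   `batch`).
#' @param alpha BH-adjusted significance level.
#' @param control_group Group label(s) defining the control stratum.
#' @return A tibble per peptide with `p_center`, `p_batch` (BH-adjusted),
#'   `status`, `rule = "confounder"`.
#' @export
confounder_filter <- function(quant, meta, alpha = 0.05,
                              control_group = "NL") {
  df <- quant %>%
    left_join(meta[, c("sample_id", "group", "center", "batch")],
              by = "sample_id") %>%
    filter(.data$group %in% control_group, !.data$missing_quant)

  test_factor <- function(values, fac) {
    fac <- droplevels(factor(fac))
    if (nlevels(fac) < 2) return(NA_real_)
    kruskal.test(values, fac)$p.value
  }

  res <- df %>%
    group_by(.data$protein, .data$peptide) %>%
    summarise(
      p_center = test_factor(.data$relative_level, .data$center),
      p_batch = test_factor(.data$relative_level, .data$batch),
      .groups = "drop"
    )
  if (nrow(res) > 0 && all(is.na(res$p_center))) {
    warn("Center has one level in the control stratum; center test skipped.")
  }
  if (nrow(res) > 0 && all(is.na(res$p_batch))) {
    warn("Batch has one level in the control stratum; batch test skipped.")
  }
  res %>%
    mutate(
      p_center = p.adjust(.data$p_center, "BH"),
      p_batch = p.adjust(.data$p_batch, "BH"),
      status = dplyr::case_when(
        is.na(.data$p_center) & is.na(.data$p_batch) ~ "unevaluable",
        (!is.na(.data$p_center) & .data$p_center < .env$alpha) |
          (!is.na(.data$p_batch) & .data$p_batch < .env$alpha) ~ "fail",
        TRUE ~ "pass"),
      rule = "confounder"
    )
}

#' Single-marker AUC screen
#'
#' Computes per-peptide orientation-free AUCs (`max(AUC, 1 - AUC)`) for
#' normal-vs-PDAC and benign-vs-PDAC, reports the direction of change, and
#' keeps peptides whose AUC in the gating comparison strictly exceeds the
#' threshold.
#'
#' @param quant Output of [quantify_transitions()].
#' @param meta Sample metadata with `sample_id`, `group`.
#' @param config A [qc_config()].
#' @return A tibble per peptide, ranked by the gating AUC, with
#'   `auc_nl_pdac`, `auc_pb_pdac`, `direction`, `status`,
#'   `rule = "auc_screen"`.
#' @export
single_marker_screen <- function(quant, meta, config = qc_config()) {
  df <- quant %>%
    left_join(meta[, c("sample_id", "group")], by = "sample_id") %>%
    filter(!.data$missing_quant)
  groups <- unique(df$group)
  if (!"PDAC" %in% groups || !any(c("NL", "PB") %in% groups)) {
    abort("Two-class labels require PDAC plus at least one control group.")
  }
  pair_auc <- function(level, group, ctrl) {
    keep <- group %in% c(ctrl, "PDAC")
    lab <- group[keep] == "PDAC"
    if (!any(lab) || all(lab)) return(NA_real_)
    roc_auc(level[keep], lab)
  }
  res <- df %>%
    group_by(.data$protein, .data$peptide) %>%
    summarise(
      auc_raw_nl = pair_auc(.data$relative_level, .data$group, "NL"),
      auc_raw_pb = pair_auc(.data$relative_level, .data$group, "PB"),
      .groups = "drop"
    ) %>%
    mutate(
      direction = dplyr::case_when(
        is.na(.data$auc_raw_nl) ~ NA_character_,
        .data$auc_raw_nl >= 0.5 ~ "up",
        TRUE ~ "down"),
      auc_nl_pdac = pmax(.data$auc_raw_nl, 1 - .data$auc_raw_nl),
      auc_pb_pdac = pmax(.data$auc_raw_pb, 1 - .data$auc_raw_pb),
      gate_auc = if (config$gate_comparison == "NL_vs_PDAC") {
        .data$auc_nl_pdac
      } else {
        .data$auc_pb_pdac
      }
    )
  res %>%
    mutate(
      status = dplyr::case_when(
        is.na(.data$gate_auc) ~ "unevaluable",
        .data$gate_auc > config$auc_screen_threshold ~ "pass",
        TRUE ~ "fail"),
      rule = "auc_screen"
    ) %>%
    select("protein", "peptide", "auc_nl_pdac", "auc_pb_pdac",
           "gate_auc", "direction", "status", "rule") %>%
    arrange(dplyr::desc(.data$gate_auc))
}

#' Run all verification filters
#'
#' Applies the CV, reference-range, interference, confounder, and
#' single-marker AUC filters — each computed on the full input, so the
#' surviving set is independent of rule order — and combines them into one
#' verdict per peptide.
#'
#' @param quant Output of [quantify_transitions()].
#' @param transitions Transition records (for the interference rule).
#' @param meta Sample metadata.
#' @param config A [qc_config()].
#' @return A tibble per peptide: per-rule statuses (`cv`, `range`,
#'   `audit`, `confounder`, `auc_screen`), `failed_rules` (list-column),
#'   and `passed` (no rule failed).
#' @export
run_qc <- function(quant, transitions, meta, config = qc_config()) {
  pieces <- list(
    cv = cv_filter(quant, config$cv_threshold),
    range = range_filter(quant, config$level_range),
    audit = audit_filter(transitions, quant, config),
    confounder = confounder_filter(quant, meta, config$confounder_alpha),
    auc_screen = single_marker_screen(quant, meta, config)
  )
  out <- purrr::reduce(
    purrr::imap(pieces, function(p, nm) {
      p <- p[, c("protein", "peptide", "status")]
      names(p)[3] <- nm
      p
    }),
    left_join, by = c("protein", "peptide")
  )
  rules <- c("cv", "range", "audit", "confounder", "auc_screen")
  out$failed_rules <- purrr::pmap(out[rules], function(...) {
    s <- c(...)
    rules[!is.na(s) & s == "fail"]
  })
  out$passed <- lengths(out$failed_rules) == 0
  out
}

#' Markers surviving QC
#' @param qc Output of [run_qc()].
#' @return Character vector of surviving protein identifiers.
#' @export
qc_survivors <- function(qc) {
  sort(unique(qc$protein[qc$passed]))
}

#' Write the per-peptide QC report
#' @param qc Output of [run_qc()].
#' @param dir Output directory.
#' @return Invisibly, the written path.
#' @export
write_qc_report <- function(qc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "qc_report.tsv")
  flat <- qc %>%
    mutate(failed_rules = purrr::map_chr(
      .data$failed_rules, paste, collapse = ";"))
  readr::write_tsv(flat, path)
  invisible(path)
}
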
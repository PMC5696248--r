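#' Stratified train/test split
#'
#' Splits samples into training and test sets at the given ratio,
#' stratified by group, stage (within PDAC), and center, deterministically
#' under the seed. Strata smaller than 2 go wholly to training with a
#' warning.
#'
#' @param meta Sample metadata with `sample_id`, `group`, and optionally
#'   `stage`, `center`.
#' @param test_fraction Fraction assigned to the test set (default 0.2,
#'   a 4:1 split).
#' @param seed Integer seed.
#' @return A list with `train` and `test` character vectors of sample ids
#'   (disjoint, exhaustive).
#' @export
split_train_test <- function(meta, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie in (0, 1).")
  }
  stage <- if ("stage" %in% names(meta)) {
    ifelse(meta$group == "PDAC", meta$stage, "")
  } else ""
  center <- if ("center" %in% names(meta)) meta$center else ""
  stratum <- paste(meta$group, stage, center, sep = "|")
  test_ids <- character()
  small <- character()
  .with_seed(seed, {
    for (s in sort(unique(stratum))) {
      ids <- meta$sample_id[stratum == s]
      if (length(ids) < 2) {
        small <- c(small, s)
        next
      }
      n_test <- round(length(ids) * test_fraction)
      if (n_test > 0) test_ids <- c(test_ids, sample(ids, n_test))
    }
  })
  if (length(small) > 0) {
    warn(sprintf("%d strata with < 2 samples assigned wholly to training.",
                 length(small)))
  }
  list(train = setdiff(meta$sample_id, test_ids), test = test_ids)
}

#' Validation scenario definitions
#'
#' The standard comparison blocks of a PDAC panel validation report:
#' control vs all PDAC, control vs stage I/II PDAC, other cancers vs
#' PDAC, pancreatic benign vs PDAC, and the same four restricted to
#' subjects within the clinically normal CA19-9 range (< 37 U/mL), where
#' CA19-9 itself carries little signal.
#'
#' @param ca199_normal_max Upper CA19-9 bound (U/mL) of the low-CA19-9
#'   scenarios.
#' @return A tibble: `name`, `control_groups` (list-column),
#'   `case_stages` (list-column, `NULL` = all stages), `ca199_max`
#'   (NA = unrestricted).
#' @export
pdac_scenarios <- function(ca199_normal_max = 37) {
  base <- tibble(
    name = c("control_vs_pdac", "control_vs_pdac_stage12",
             "other_cancer_vs_pdac", "benign_vs_pdac"),
    control_groups = list("NL", "NL", "OC", "PB"),
    case_stages = list(NULL, c("I", "II"), NULL, NULL)
  )
  bind_rows(
    mutate(base, ca199_max = NA_real_),
    mutate(base, name = paste0(.data$name, "_low_ca199"),
           ca199_max = ca199_normal_max)
  )
}

# apply one scenario's filters to a cohort table; returns row index
.scenario_rows <- function(data, scenario) {
  case <- data$group == "PDAC"
  if (!is.null(scenario$case_stages[[1]])) {
    case <- case & data$stage %in% scenario$case_stages[[1]]
  }
  control <- data$group %in% scenario$control_groups[[1]]
  keep <- case | control
  if (!is.na(scenario$ca199_max)) {
    keep <- keep & !is.na(data$ca199) & data$ca199 < scenario$ca199_max
  }
  keep
}

#' Scenario-based evaluation of a frozen panel
#'
#' Applies a trained panel model — with its frozen decision cutoff — and
#' the anchor marker alone to a test cohort under each scenario's filters,
#' reporting AUC, sensitivity and specificity at the transferred cutoffs,
#' paired DeLong and McNemar comparisons, and the PPV at a population
#' prevalence. All statistics are computed on test data only. Scenarios
#' with fewer than 2 samples in either class are reported unevaluable and
#' the run continues.
#'
#' @param model A `panel_model` trained (and its cutoff frozen) on the
#'   training set.
#' @param data Test-cohort tibble: `sample_id`, `group`, `stage`,
#'   `ca199`, and the panel marker columns.
#' @param scenarios A [pdac_scenarios()]-style tibble.
#' @param anchor Column holding the anchor marker value (scored as
#'   `log10(value)`).
#' @param anchor_cutoff Frozen anchor decision cutoff on the `log10`
#'   scale (from the training set); `NULL` skips anchor sensitivity.
#' @param prevalence Population prevalence used for the PPV.
#' @return An `eval_report` tibble: one row per scenario with panel and
#'   anchor statistics.
#' @export
run_scenarios <- function(model, data, scenarios = pdac_scenarios(),
                          anchor = "ca199", anchor_cutoff = NULL,
                          prevalence = 12.9e-5) {
  rows <- purrr::map(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    keep <- .scenario_rows(data, sc)
    sub <- data[keep, , drop = FALSE]
    labels <- sub$group == "PDAC"
    panel_scores <- predict(model, sub)
    anchor_scores <- log10(sub[[anchor]])
    ok <- !is.na(panel_scores) & !is.na(anchor_scores) & !is.na(labels)
    sub <- sub[ok, ]; labels <- labels[ok]
    panel_scores <- panel_scores[ok]; anchor_scores <- anchor_scores[ok]
    base <- tibble(scenario = sc$name, n_cases = sum(labels),
                   n_controls = sum(!labels))
    if (sum(labels) < 2 || sum(!labels) < 2) {
      return(mutate(base, evaluable = FALSE))
    }
    dl <- delong_test(panel_scores, anchor_scores, labels)
    panel_at <- apply_cutoff(panel_scores, labels, model$cutoff)
    res <- mutate(
      base, evaluable = TRUE,
      auc_panel = dl$auc_a, auc_anchor = dl$auc_b,
      auc_gain = dl$auc_diff, delong_p = dl$p_value,
      sens_panel = panel_at$sensitivity, spec_panel = panel_at$specificity,
      ppv_panel = ppv(panel_at$sensitivity, panel_at$specificity,
                      prevalence)
    )
    if (!is.null(anchor_cutoff)) {
      anchor_at <- apply_cutoff(anchor_scores, labels, anchor_cutoff)
      mc <- mcnemar_test(panel_at$predictions, anchor_at$predictions,
                         labels, scope = "cases")
      res <- mutate(
        res,
        sens_anchor = anchor_at$sensitivity,
        spec_anchor = anchor_at$specificity,
        sens_gain = .data$sens_panel - anchor_at$sensitivity,
        mcnemar_p = mc$p_value,
        ppv_anchor = ppv(anchor_at$sensitivity, anchor_at$specificity,
                         prevalence)
      )
    }
    res
  })
  out <- bind_rows(rows)
  class(out) <- c("eval_report", class(out))
  out
}

#' Write a scenario report and its figures
#'
#' Writes the per-scenario statistics as TSV and, when marker data are
#' given, per-marker box plots on log axes and per-scenario ROC overlays
#' (panel vs anchor) as PDF figures.
#'
#' @param report An `eval_report` from [run_scenarios()].
#' @param dir Output directory.
#' @param model Optional `panel_model` for the ROC overlays.
#' @param data Optional test-cohort tibble (enables figures).
#' @param anchor Anchor column name.
#' @return Invisibly, the written file paths.
#' @export
render_report <- function(report, dir, model = NULL, data = NULL,
                          anchor = "ca199") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "scenario_report.tsv")
  readr::write_tsv(as_tibble(report), tsv)
  paths <- c(report = tsv)
  if (!is.null(model) && !is.null(data)) {
    box <- file.path(dir, "marker_boxplots.pdf")
    ggplot2::ggsave(box, plot_marker_levels(data, model$markers),
                    width = 8, height = 4)
    roc <- file.path(dir, "roc_curves.pdf")
    ggplot2::ggsave(roc, plot_roc_curves(model, data, anchor = anchor),
                    width = 8, height = 6)
    paths <- c(paths, boxplots = box, roc = roc)
  }
  invisible(paths)
}

#' Box plots of marker levels by disease group
#'
#' @param data Cohort tibble with `group` and the marker columns.
#' @param markers Marker columns to plot (log-scale y axis).
#' @return A ggplot object.
#' @export
plot_marker_levels <- function(data, markers) {
  long <- data %>%
    select("group", dplyr::all_of(markers)) %>%
    tidyr::pivot_longer(-"group", names_to = "marker",
                        values_to = "level") %>%
    filter(is.finite(.data$level), .data$level > 0)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$level)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative level (log scale)") +
    ggplot2::theme_bw()
}

#' ROC overlays for panel vs anchor
#'
#' @param model A `panel_model`.
#' @param data Test-cohort tibble (`group`, marker columns, anchor
#'   column).
#' @param scenarios Scenario tibble; defaults to the unrestricted blocks.
#' @param anchor Anchor column name.
#' @return A ggplot object with one facet per scenario.
#' @export
plot_roc_curves <- function(model, data,
                            scenarios = head(pdac_scenarios(), 4),
                            anchor = "ca199") {
  curves <- purrr::map_dfr(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    sub <- data[.scenario_rows(data, sc), , drop = FALSE]
    labels <- sub$group == "PDAC"
    ps <- predict(model, sub)
    as_ <- log10(sub[[anchor]])
    ok_p <- !is.na(ps); ok_a <- !is.na(as_)
    if (sum(labels[ok_p]) < 2 || sum(!labels[ok_p]) < 2) return(NULL)
    bind_rows(
      mutate(roc_curve(ps[ok_p], labels[ok_p]), classifier = "panel"),
      mutate(roc_curve(as_[ok_a], labels[ok_a]), classifier = "anchor")
    ) %>% mutate(scenario = sc$name)
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       color = .data$classifier)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted", color = "grey60") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_bw()
}

#' @export
autoplot.eval_report <- function(object, ...) {
  df <- object %>%
    filter(.data$evaluable) %>%
    select("scenario", "auc_panel", "auc_anchor") %>%
    tidyr::pivot_longer(-"scenario", names_to = "classifier",
                        names_prefix = "auc_", values_to = "auc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$auc,
                                   fill = .data$classifier)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "test-set AUC") +
    ggplot2::theme_bw()
}

#' Assemble the sample-by-marker analysis table
#'
#' Joins the quantified MRM marker matrix with the metadata columns the
#' evaluation needs (`group`, `stage`, `center`, `batch`, `ca199`,
#' `is_case`), giving the single wide table that panel search and
#' scenario evaluation consume.
#'
#' @param quant_wide Output of [quant_matrix()].
#' @param meta Sample metadata from [generate_cohort()] (or of the same
#'   layout).
#' @return A tibble, one row per sample.
#' @export
assemble_analysis_table <- function(quant_wide, meta) {
  cols <- intersect(c("sample_id", "group", "stage", "center", "batch",
                      "ca199", "ca199_censored", "ca199_missing",
                      "is_case"), names(meta))
  left_join(quant_wide, meta[, cols], by = "sample_id")
}
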
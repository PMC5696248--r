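#' Pick the signature transition of a peptide
#'
#' The transition used for quantitation is the one with the highest total
#' light-channel peak area across all samples and replicates, chosen once
#' globally per peptide so the quant series stays internally comparable.
#' Ties break lexicographically on `transition_id`.
#'
#' @param records Transition records for a single peptide.
#' @return The signature `transition_id` (length-1 character).
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   transition_id = c("t1", "t2", "t3"),
#'   area_light = c(100, 300, 50)
#' )
#' select_signature_transition(recs)
select_signature_transition <- function(records) {
  if (nrow(records) == 0 || all(!is.finite(records$area_light))) {
    abort(sprintf("No finite light-channel signal for peptide '%s'.",
                  if (nrow(records)) records$peptide[1] else "?"))
  }
  totals <- records %>%
    filter(is.finite(.data$area_light)) %>%
    group_by(.data$transition_id) %>%
    summarise(total = sum(.data$area_light), .groups = "drop") %>%
    arrange(dplyr::desc(.data$total), .data$transition_id)
  totals$transition_id[1]
}

#' Relative peptide level of one transition measurement
#'
#' The dimensionless endogenous:standard peak-area ratio: light area over
#' the heavy (stable-isotope standard) area, or over the external-standard
#' (beta-galactosidase) area, depending on `mode`. Vectorized. A zero or
#' missing denominator yields `NA` (flagged missing downstream, never an
#' error that aborts a batch); a zero numerator yields 0, which callers
#' flag as below detection.
#'
#' @param area_light Light-channel areas.
#' @param area_denom Heavy or external-standard areas, matching `mode`.
#' @return Numeric vector of ratios.
#' @export
#' @examples
#' relative_level(500, 250)   # 2.0
relative_level <- function(area_light, area_denom) {
  out <- ifelse(!is.finite(area_denom) | area_denom <= 0,
                NA_real_, area_light / area_denom)
  as.numeric(out)
}

#' Aggregate technical replicates of a ratio
#'
#' Mean and coefficient of variation (sample SD over mean, on the raw
#' untransformed ratios) across replicates. A single replicate yields an
#' `NA` CV; a zero mean leaves the CV undefined.
#'
#' @param x Per-replicate relative levels.
#' @return A list with `mean` and `cv`.
#' @export
#' @examples
#' aggregate_replicates(c(1, 2, 3))  # mean 2, cv 0.5
aggregate_replicates <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(list(mean = NA_real_, cv = NA_real_))
  m <- mean(x)
  cv <- if (length(x) < 2 || m == 0) NA_real_ else sd(x) / m
  list(mean = m, cv = cv)
}

#' Quantify peptides from a transition report
#'
#' Turns transition-level peak areas into per-sample relative peptide
#' levels: selects one signature transition per peptide (highest total
#' light area), ratios the light channel to the stable-isotope standard
#' (or external standard), and aggregates technical replicates into a
#' mean level and replicate CV.
#'
#' @param transitions Tibble of transition records (`sample_id`,
#'   `replicate`, `protein`, `peptide`, `transition_id`, `area_light`,
#'   `area_heavy`, optionally `area_external_standard`).
#' @param mode `"sis"` (light:heavy ratio, default) or `"external"`
#'   (light:external-standard).
#' @param exclude_transitions Optional tibble (`peptide`, `transition_id`)
#'   of transitions to drop before signature selection — typically the
#'   interfered pairs from [audit_flag()], so quantitation runs on
#'   interference-free transitions.
#' @return A tibble with one row per sample x peptide: `sample_id`,
#'   `protein`, `peptide`, `signature_transition`, `relative_level`,
#'   `replicate_cv`, `n_replicates`, `below_detection`, `missing_quant`,
#'   and a `normalization_mode` attribute.
#' @export
quantify_transitions <- function(transitions, mode = c("sis", "external"),
                                 exclude_transitions = NULL) {
  mode <- match.arg(mode)
  denom_col <- if (mode == "sis") "area_heavy" else "area_external_standard"
  if (!denom_col %in% names(transitions)) {
    abort(sprintf("Column '%s' required for mode '%s'.", denom_col, mode))
  }
  if (!is.null(exclude_transitions) && nrow(exclude_transitions) > 0) {
    drop_key <- paste(exclude_transitions$peptide,
                      exclude_transitions$transition_id)
    kept <- !(paste(transitions$peptide, transitions$transition_id) %in%
                drop_key)
    # never drop a peptide entirely: keep all its transitions instead
    fully_dropped <- setdiff(unique(transitions$peptide),
                             unique(transitions$peptide[kept]))
    kept <- kept | transitions$peptide %in% fully_dropped
    transitions <- transitions[kept, , drop = FALSE]
  }

  sig <- transitions %>%
    group_by(.data$protein, .data$peptide) %>%
    tidyr::nest() %>%
    mutate(signature_transition =
             purrr::map_chr(.data$data, select_signature_transition)) %>%
    select(-"data") %>%
    ungroup()

  out <- transitions %>%
    dplyr::inner_join(sig, by = c("protein", "peptide")) %>%
    filter(.data$transition_id == .data$signature_transition) %>%
    mutate(ratio = relative_level(.data$area_light, .data[[denom_col]])) %>%
    group_by(.data$sample_id, .data$protein, .data$peptide,
             .data$signature_transition) %>%
    summarise(
      n_replicates = sum(is.finite(.data$ratio)),
      relative_level = ifelse(.data$n_replicates > 0,
                              mean(.data$ratio[is.finite(.data$ratio)]),
                              NA_real_),
      replicate_cv = ifelse(
        .data$n_replicates > 1 & is.finite(.data$relative_level) &
          .data$relative_level != 0,
        sd(.data$ratio[is.finite(.data$ratio)]) / .data$relative_level,
        NA_real_),
      .groups = "drop"
    ) %>%
    mutate(
      below_detection = is.finite(.data$relative_level) &
        .data$relative_level == 0,
      missing_quant = !is.finite(.data$relative_level)
    )
  attr(out, "normalization_mode") <- mode
  out
}

#' Reshape quantities into a sample-by-peptide matrix
#'
#' @param quant Output of [quantify_transitions()].
#' @param value Column to spread, `"relative_level"` by default. Proteins
#'   are used as column names when each protein has a single peptide,
#'   otherwise peptides.
#' @return A wide tibble, samples as rows.
#' @export
quant_matrix <- function(quant, value = "relative_level") {
  key <- if (anyDuplicated(distinct(quant, .data$protein,
                                    .data$peptide)$protein)) {
    "peptide"
  } else "protein"
  quant %>%
    mutate(lvl = ifelse(.data$missing_quant, NA_real_, .data[[value]])) %>%
    select("sample_id", dplyr::all_of(key), "lvl") %>%
    tidyr::pivot_wider(names_from = dplyr::all_of(key),
                       values_from = "lvl")
}

#' Write quantitation outputs
#'
#' Writes the sample-by-peptide quant matrix and a per-peptide QC summary
#' (median level, median replicate CV, missing counts) as TSVs.
#'
#' @param quant Output of [quantify_transitions()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_quantitation <- function(quant, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat_path <- file.path(dir, "quant_matrix.tsv")
  qc_path <- file.path(dir, "peptide_summary.tsv")
  readr::write_tsv(quant_matrix(quant), mat_path)
  summary <- quant %>%
    group_by(.data$protein, .data$peptide, .data$signature_transition) %>%
    summarise(
      median_level = median(.data$relative_level, na.rm = TRUE),
      median_cv = median(.data$replicate_cv, na.rm = TRUE),
      n_missing = sum(.data$missing_quant),
      n_below_detection = sum(.data$below_detection),
      .groups = "drop"
    )
  readr::write_tsv(summary, qc_path)
  invisible(c(matrix = mat_path, summary = qc_path))
}
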
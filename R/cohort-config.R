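#' Multi-center validation study design
#'
#' The default cohort layout: per-group, per-center sample counts for a
#' four-group pancreatic-cancer validation study (401 pancreatic ductal
#' adenocarcinoma, 349 normal controls, 149 other cancers, 109 pancreatic
#' benign disease; 1008 samples over five clinical centers), together with
#' per-stratum CA19-9 medians and MADs (U/mL) used to calibrate the
#' immunoassay channel of the generator.
#'
#' @return A tibble with columns `group`, `center`, `n`, `ca199_median`,
#'   `ca199_mad`.
#' @export
#' @examples
#' sum(validation_design()$n)
validation_design <- function() {
  tibble(
    group = c(rep("PDAC", 5), "NL", "OC", rep("PB", 4)),
    center = c("NCC", "AMC", "SNUH", "YSH", "SMC",
               "SNUH", "SNUH",
               "YSH", "AMC", "SMC", "SNU"),
    n = c(128L, 75L, 50L, 47L, 101L, 349L, 149L, 27L, 47L, 30L, 5L),
    ca199_median = c(312.5, 51.7, 82.85, 59.3, 363.45,
                     7.4, 9.5, 7.5, 7, 9.33, 11),
    ca199_mad = c(8032.5, 415.05, 358.68, 328.9, 1531.29,
                  3.6, 12.5, 9.55, 17.3, 8.38, 27.9)
  )
}

#' @noRd
.default_stages <- function() {
  tibble(stage = c("I", "II", "III", "IV"), n = c(20L, 228L, 31L, 122L))
}

# group-level demographics (age mean/sd, male fraction, BMI mean/sd),
# pooled across centers
.demographics <- tibble(
  group = c("PDAC", "NL", "OC", "PB"),
  age_mean = c(61.5, 56.9, 55.2, 50.9),
  age_sd = c(10.3, 8.1, 11.5, 13.9),
  male_frac = c(0.62, 0.56, 0.26, 0.37),
  bmi_mean = c(22.9, 23.8, 23.4, 23.2),
  bmi_sd = c(3.1, 3.1, 3.4, 3.7)
)

#' Specify one synthetic marker
#'
#' Defines the log-normal generative model of a single MRM marker: a common
#' log-scale spread, a disease effect (given directly or via a target
#' single-marker AUC), and optional batch / center nuisance effects used by
#' the confounder-recovery machinery.
#'
#' @param name Marker (protein) identifier.
#' @param direction `"up"` (elevated in cases), `"down"`, or `"null"`.
#' @param target_auc Target case-vs-control AUC of the raw level; converted
#'   to a log-scale shift via [effect_for_auc()]. Ignored when `effect` is
#'   given. Required (or `effect`) unless `direction = "null"`.
#' @param effect Log-scale location shift applied to cases (sign taken from
#'   `direction`).
#' @param base_meanlog Log-scale location of the control population. The
#'   default 0 puts the control median relative level at 1.
#' @param sdlog Common log-scale standard deviation, > 0.
#' @param n_transitions Number of transitions monitored for the peptide.
#' @param batch_fold Multiplicative batch artifact: levels in even-numbered
#'   batches are scaled by this factor (1 = no batch effect).
#' @param center_fold Multiplicative center artifact applied to alternating
#'   centers (1 = none).
#' @return A one-row tibble (a marker-specification fragment).
#' @export
#' @examples
#' marker_spec("LRG1", "up", target_auc = 0.70)
marker_spec <- function(name, direction = c("null", "up", "down"),
                        target_auc = NULL, effect = NULL,
                        base_meanlog = 0, sdlog = 0.5,
                        n_transitions = 3L, batch_fold = 1,
                        center_fold = 1) {
  direction <- match.arg(direction)
  .assert_positive(sdlog, "sdlog")
  .assert_positive(batch_fold, "batch_fold")
  .assert_positive(center_fold, "center_fold")
  if (n_transitions < 1) abort("`n_transitions` must be a positive integer.")
  if (is.null(effect)) {
    effect <- if (direction == "null" || is.null(target_auc)) 0
              else effect_for_auc(target_auc, sdlog)
  }
  if (direction == "null") effect <- 0
  tibble(
    name = as.character(name), direction = direction,
    effect = effect, base_meanlog = base_meanlog, sdlog = sdlog,
    n_transitions = as.integer(n_transitions),
    batch_fold = batch_fold, center_fold = center_fold
  )
}

#' Default marker panel specification
#'
#' Two informative markers emulating the leucine-rich alpha-2 glycoprotein 1
#' (up in PDAC) and transthyretin (down in PDAC) plasma signals, each
#' calibrated to a single-marker AUC of 0.70, plus `n_decoys` null markers.
#'
#' @param n_decoys Number of uninformative decoy markers to append.
#' @param informative_auc Target single-marker AUC of the two informative
#'   markers.
#' @return A tibble of marker specifications.
#' @export
default_marker_specs <- function(n_decoys = 20L, informative_auc = 0.70) {
  specs <- bind_rows(
    marker_spec("LRG1", "up", target_auc = informative_auc),
    marker_spec("TTR", "down", target_auc = informative_auc)
  )
  if (n_decoys > 0) {
    specs <- bind_rows(
      specs,
      purrr::map_dfr(seq_len(n_decoys),
                     function(i) marker_spec(sprintf("DEC%02d", i), "null"))
    )
  }
  specs
}

#' Configure a synthetic cohort
#'
#' Bundles every knob of the synthetic multi-center cohort and MRM data
#' generator: the study design (group-by-center sample counts and CA19-9
#' robust statistics), the PDAC stage distribution, the marker
#' specifications, the CA19-9 assay model (non-expressor fraction, censor
#' bounds and forced-censor rate, missingness), and the technical layer
#' (triplicate replicate CV, transition interference, blocked batches).
#'
#' @param group_sizes Tibble with columns `group`, `center`, `n` and
#'   optionally `ca199_median`, `ca199_mad`; defaults to
#'   [validation_design()].
#' @param stage_distribution Tibble `stage`, `n` for the PDAC group; counts
#'   must sum to the PDAC total.
#' @param marker_specs Tibble of [marker_spec()] rows.
#' @param nonexpressor_fraction Fraction of PDAC cases whose CA19-9 is drawn
#'   from the control distribution (Lewis-antigen-negative phenotype;
#'   clinically 10--15%).
#' @param ca199_censor_rate Fraction of samples whose CA19-9 is forced onto
#'   the nearer assay bound (and flagged censored), on top of natural
#'   clamping.
#' @param ca199_bounds Length-2 numeric: lower and upper assay reporting
#'   bounds in U/mL.
#' @param missing_rate Fraction of CA19-9 measurements set missing
#'   (flagged, never silently zero).
#' @param n_replicates Technical replicates per sample (triplicate default).
#' @param replicate_cv Multiplicative replicate CV of the light-channel
#'   areas (hence of the light:heavy ratio).
#' @param interference_rate Fraction of (peptide, transition) pairs that
#'   receive an additive light-channel-only interference.
#' @param interference_strength Interference bias as a multiple of the
#'   expected light area at relative level 1.
#' @param batch_size Samples per preparation batch (blocked randomization).
#' @param seed Mandatory integer seed; generation is bit-reproducible.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' sum(cfg$group_sizes$n)
cohort_config <- function(group_sizes = validation_design(),
                          stage_distribution = .default_stages(),
                          marker_specs = default_marker_specs(),
                          nonexpressor_fraction = 0.125,
                          ca199_censor_rate = 0.05,
                          ca199_bounds = c(1.2, 10000),
                          missing_rate = 0.02,
                          n_replicates = 3L,
                          replicate_cv = 0.08,
                          interference_rate = 0.05,
                          interference_strength = 1,
                          batch_size = 24L,
                          seed) {
  if (missing(seed)) abort("`seed` is mandatory in a cohort configuration.")
  group_sizes <- as_tibble(group_sizes)
  if (!all(c("group", "center", "n") %in% names(group_sizes))) {
    abort("`group_sizes` needs columns group, center, n.")
  }
  if (any(group_sizes$n < 0)) abort("Group sizes must be non-negative.")
  n_pdac <- sum(group_sizes$n[group_sizes$group == "PDAC"])
  if (n_pdac > 0) {
    if (is.null(stage_distribution) || sum(stage_distribution$n) != n_pdac) {
      # rescale the default stage mix to the requested PDAC count
      ref <- .default_stages()
      raw <- ref$n / sum(ref$n) * n_pdac
      n_stage <- floor(raw)
      rem <- n_pdac - sum(n_stage)
      if (rem > 0) {
        top <- order(raw - n_stage, decreasing = TRUE)[seq_len(rem)]
        n_stage[top] <- n_stage[top] + 1L
      }
      stage_distribution <- tibble(stage = ref$stage, n = as.integer(n_stage))
    }
  } else {
    stage_distribution <- tibble(stage = character(), n = integer())
  }
  .assert_fraction(nonexpressor_fraction, "nonexpressor_fraction")
  .assert_fraction(ca199_censor_rate, "ca199_censor_rate")
  .assert_fraction(missing_rate, "missing_rate")
  .assert_fraction(interference_rate, "interference_rate")
  .assert_positive(replicate_cv, "replicate_cv", strict = FALSE)
  if (length(ca199_bounds) != 2 || ca199_bounds[1] >= ca199_bounds[2]) {
    abort("`ca199_bounds` must be c(lower, upper) with lower < upper.")
  }
  if (n_replicates < 1) abort("`n_replicates` must be positive.")
  marker_specs <- as_tibble(marker_specs)
  if (nrow(marker_specs) > 0 && anyDuplicated(marker_specs$name)) {
    abort("Marker names must be unique.")
  }
  structure(
    list(group_sizes = group_sizes,
         stage_distribution = stage_distribution,
         marker_specs = marker_specs,
         nonexpressor_fraction = nonexpressor_fraction,
         ca199_censor_rate = ca199_censor_rate,
         ca199_bounds = ca199_bounds,
         missing_rate = missing_rate,
         n_replicates = as.integer(n_replicates),
         replicate_cv = replicate_cv,
         interference_rate = interference_rate,
         interference_strength = interference_strength,
         batch_size = as.integer(batch_size),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  samples:", sum(x$group_sizes$n), "in",
      nrow(x$group_sizes), "group x center strata\n")
  cat("  markers:", nrow(x$marker_specs),
      sprintf("(%d informative)",
              sum(x$marker_specs$direction != "null")), "\n")
  cat("  replicates:", x$n_replicates,
      " replicate CV:", x$replicate_cv,
      " interference rate:", x$interference_rate, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
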
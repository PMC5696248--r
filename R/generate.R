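#' Generate a synthetic multi-center cohort
#'
#' Draws sample metadata for the configured study design: group, center,
#' AJCC stage (PDAC only), demographics, blocked-randomized preparation
#' batch, and a CA19-9 immunoassay value with censor and missing flags.
#' CA19-9 is log-normal per group-by-center stratum with the log-location
#' set to the configured median (so generated medians converge to the
#' configured ones) and the log-spread calibrated from the configured MAD
#' via [lnorm_sdlog_from_mad()]. A configured fraction of PDAC cases are
#' CA19-9 non-expressors whose value is drawn from the control
#' distribution; their identities are recorded in the ground truth.
#'
#' @param config A [cohort_config()].
#' @return A list with `meta` (one tibble row per sample: `sample_id`,
#'   `group`, `center`, `stage`, `batch`, `age`, `sex`, `bmi`, `ca199`,
#'   `ca199_censored`, `ca199_missing`, `is_case`) and `truth` (latent
#'   labels: `nonexpressors`, `informative_markers`,
#'   `batch_affected_markers`, `class_labels`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' table(cohort$meta$group)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  gs <- config$group_sizes
  if (sum(gs$n) == 0) {
    return(list(
      meta = tibble(sample_id = character(), group = character(),
                    center = character(), stage = character(),
                    batch = character(), age = numeric(), sex = character(),
                    bmi = numeric(), ca199 = numeric(),
                    ca199_censored = logical(), ca199_missing = logical(),
                    is_case = logical()),
      truth = list(nonexpressors = character(),
                   informative_markers = character(),
                   batch_affected_markers = character(),
                   class_labels = tibble(sample_id = character(),
                                         is_case = logical()))
    ))
  }

  .with_seed(config$seed, {
    meta <- gs[rep(seq_len(nrow(gs)), gs$n), c("group", "center")]
    meta <- as_tibble(meta)
    n <- nrow(meta)
    meta$sample_id <- sprintf("S%04d", seq_len(n))

    # AJCC stage within PDAC
    meta$stage <- NA_character_
    pdac_idx <- which(meta$group == "PDAC")
    if (length(pdac_idx) > 0) {
      stages <- rep(config$stage_distribution$stage,
                    config$stage_distribution$n)
      meta$stage[pdac_idx] <- sample(stages, length(pdac_idx))
    }

    # demographics (generated to match the design margins; not used by
    # any classifier in the pipeline)
    demo <- .demographics[match(meta$group, .demographics$group), ]
    meta$age <- round(rnorm(n, demo$age_mean, demo$age_sd), 1)
    meta$sex <- ifelse(runif(n) < demo$male_frac, "M", "F")
    meta$bmi <- round(rnorm(n, demo$bmi_mean, demo$bmi_sd), 1)

    # blocked randomization into preparation batches
    meta$batch <- .blocked_batches(meta$group, config$batch_size)

    # CA19-9 parameters per stratum
    if (!all(c("ca199_median", "ca199_mad") %in% names(gs))) {
      gs$ca199_median <- ifelse(gs$group == "PDAC", 120, 8)
      gs$ca199_mad <- ifelse(gs$group == "PDAC", 300, 5)
    }
    gs$meanlog <- log(gs$ca199_median)
    gs$sdlog <- purrr::map2_dbl(gs$ca199_median, gs$ca199_mad,
                                lnorm_sdlog_from_mad)
    stratum <- match(paste(meta$group, meta$center),
                     paste(gs$group, gs$center))
    meanlog <- gs$meanlog[stratum]
    sdlog <- gs$sdlog[stratum]

    # non-expressing PDAC cases draw from the control distribution
    nonexp <- rep(FALSE, n)
    ctrl <- gs[gs$group == "NL", , drop = FALSE]
    if (nrow(ctrl) == 0) ctrl <- gs[gs$group != "PDAC", , drop = FALSE]
    if (length(pdac_idx) > 0 && nrow(ctrl) > 0 &&
        config$nonexpressor_fraction > 0) {
      nonexp[pdac_idx] <- runif(length(pdac_idx)) <
        config$nonexpressor_fraction
      ne_idx <- which(nonexp)
      if (length(ne_idx) > 0) {
        pick <- ctrl[sample.int(nrow(ctrl), length(ne_idx), replace = TRUE,
                                prob = ctrl$n + 1e-9), ]
        meanlog[ne_idx] <- pick$meanlog
        sdlog[ne_idx] <- pick$sdlog
      }
    }

    ca199 <- rlnorm(n, meanlog, sdlog)

    # forced censoring onto the nearer assay bound, then natural clamping
    lo <- config$ca199_bounds[1]; hi <- config$ca199_bounds[2]
    forced <- runif(n) < config$ca199_censor_rate
    ca199[forced] <- ifelse(exp(meanlog[forced]) < 37, lo / 2, hi * 2)
    censored <- ca199 <= lo | ca199 >= hi
    ca199 <- pmin(pmax(ca199, lo), hi)

    missing <- runif(n) < config$missing_rate
    ca199[missing] <- NA_real_
    censored[missing] <- NA

    meta$ca199 <- ca199
    meta$ca199_censored <- censored
    meta$ca199_missing <- missing
    meta$is_case <- meta$group == "PDAC"
    meta <- meta[, c("sample_id", "group", "center", "stage", "batch",
                     "age", "sex", "bmi", "ca199", "ca199_censored",
                     "ca199_missing", "is_case")]

    specs <- config$marker_specs
    truth <- list(
      nonexpressors = meta$sample_id[nonexp],
      informative_markers = specs$name[specs$direction != "null"],
      batch_affected_markers = specs$name[specs$batch_fold != 1],
      class_labels = meta[, c("sample_id", "is_case")]
    )
    list(meta = meta, truth = truth)
  })
}

# latent log-scale location for each sample x marker combination
.marker_meanlog <- function(meta, spec) {
  shift <- switch(spec$direction, up = spec$effect,
                  down = -spec$effect, 0)
  ml <- spec$base_meanlog + ifelse(meta$is_case, shift, 0)
  if (spec$batch_fold != 1) {
    batch_num <- as.integer(sub("^B", "", meta$batch))
    ml <- ml + ifelse(batch_num %% 2 == 0, log(spec$batch_fold), 0)
  }
  if (spec$center_fold != 1) {
    centers <- sort(unique(meta$center))
    affected <- centers[seq_along(centers) %% 2 == 0]
    ml <- ml + ifelse(meta$center %in% affected, log(spec$center_fold), 0)
  }
  ml
}

#' Generate latent marker levels directly
#'
#' Draws the per-sample latent relative levels of every configured marker
#' (the quantity that transition-level simulation and quantitation recover
#' up to technical noise), as a wide sample-by-marker tibble. Useful for
#' marker-level benchmarking where the technical replication layer is not
#' under study.
#'
#' @param meta Sample metadata from [generate_cohort()].
#' @param config The [cohort_config()].
#' @param seed Optional seed override (defaults to `config$seed + 1`).
#' @return A tibble with `sample_id` and one column per marker.
#' @export
generate_marker_matrix <- function(meta, config, seed = config$seed + 1) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- config$marker_specs
  .with_seed(seed, {
    out <- tibble(sample_id = meta$sample_id)
    for (i in seq_len(nrow(specs))) {
      spec <- specs[i, ]
      ml <- .marker_meanlog(meta, spec)
      out[[spec$name]] <- rlnorm(nrow(meta), ml, spec$sdlog)
    }
    out
  })
}

#' Generate transition-level MRM data
#'
#' Simulates a Skyline-export-style transition report: for every sample,
#' marker, transition, and technical replicate, a light (endogenous) and
#' heavy (stable-isotope standard) peak area. Heavy areas are constant per
#' transition; light areas are latent abundance times a per-transition
#' response times multiplicative log-normal replicate noise with the
#' configured CV. A random `interference_rate` fraction of
#' (peptide, transition) pairs receive an additive light-channel-only bias
#' that distorts the light transition-ratio pattern relative to heavy —
#' the signature that interference detection looks for. The interfered
#' pairs, per-transition responses, and latent levels are returned as
#' ground truth.
#'
#' @param meta Sample metadata from [generate_cohort()]; must be non-empty.
#' @param config The [cohort_config()].
#' @param seed Optional seed override (defaults to `config$seed + 1`;
#'   latent levels match [generate_marker_matrix()] under the same seed).
#' @return A list with `transitions` (tibble: `sample_id`, `replicate`,
#'   `batch`, `protein`, `peptide`, `transition_id`, `area_light`,
#'   `area_heavy`, `area_external_standard`) and `truth`
#'   (`interfered_transitions`, `transition_responses`, `latent_levels`).
#' @export
generate_transition_data <- function(meta, config, seed = config$seed + 1) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(meta) == 0) abort("`meta` must be non-empty.")
  specs <- config$marker_specs
  if (nrow(specs) == 0) abort("No markers configured.")
  heavy_base <- 1e5
  external_base <- 5e4
  cv <- config$replicate_cv
  sdlog_rep <- if (cv > 0) sqrt(log(1 + cv^2)) else 0

  latent <- generate_marker_matrix(meta, config, seed = seed)

  .with_seed(seed + 1, {
    per_marker <- purrr::map(seq_len(nrow(specs)), function(i) {
      spec <- specs[i, ]
      k <- spec$n_transitions
      resp <- runif(k, 0.2, 1)
      resp <- resp / sum(resp)
      tid <- sprintf("%s_1.t%02d", spec$name, seq_len(k))
      interfered <- runif(k) < config$interference_rate
      grid <- tidyr::expand_grid(
        sample_id = meta$sample_id,
        transition = seq_len(k),
        replicate = seq_len(config$n_replicates)
      )
      lat <- latent[[spec$name]][match(grid$sample_id, latent$sample_id)]
      r <- resp[grid$transition]
      noise <- if (sdlog_rep > 0) {
        exp(rnorm(nrow(grid), -sdlog_rep^2 / 2, sdlog_rep))
      } else 1
      light <- lat * heavy_base * r * noise
      bias <- ifelse(interfered[grid$transition],
                     config$interference_strength * heavy_base * r, 0)
      tibble(
        sample_id = grid$sample_id,
        replicate = grid$replicate,
        protein = spec$name,
        peptide = paste0(spec$name, "_1"),
        transition_id = tid[grid$transition],
        area_light = light + bias,
        area_heavy = heavy_base * r,
        area_external_standard = external_base,
        .interfered = interfered[grid$transition],
        .response = r
      )
    })
    all <- bind_rows(per_marker)
    all$batch <- meta$batch[match(all$sample_id, meta$sample_id)]

    truth <- list(
      interfered_transitions = distinct(
        all[all$.interfered, c("peptide", "transition_id")]),
      transition_responses = distinct(
        all[, c("peptide", "transition_id", ".response")]) %>%
        rename(response = ".response"),
      latent_levels = tidyr::pivot_longer(
        latent, -"sample_id", names_to = "protein", values_to = "level")
    )
    transitions <- all[, c("sample_id", "replicate", "batch", "protein",
                           "peptide", "transition_id", "area_light",
                           "area_heavy", "area_external_standard")]
    list(transitions = as_tibble(transitions), truth = truth)
  })
}

#' Emulate an orthogonal immunoassay measurement channel
#'
#' Produces immunoassay-like absolute concentrations from quantified MRM
#' relative levels: a monotone (log-linear) transform of the latent
#' abundance plus independent log-normal noise scaled so the log-scale
#' Pearson correlation with the MRM ratios hits a configurable target.
#'
#' @param quant Peptide quantities (long tibble with `sample_id`, `protein`,
#'   `relative_level`), e.g. from [quantify_transitions()].
#' @param target_r Target log-scale Pearson correlation with the MRM
#'   ratios, in (0, 1]; 1 means a noiseless monotone transform.
#' @param scale_ngml Multiplicative constant mapping relative level 1 to an
#'   ng/mL-like concentration.
#' @param seed Integer seed.
#' @return A tibble `sample_id`, `protein`, `concentration`.
#' @export
generate_second_platform <- function(quant, target_r = 0.9,
                                     scale_ngml = 1000, seed = 1) {
  if (nrow(quant) == 0) {
    return(tibble(sample_id = character(), protein = character(),
                  concentration = numeric()))
  }
  if (target_r <= 0 || target_r > 1) abort("`target_r` must be in (0, 1].")
  .with_seed(seed, {
    quant %>%
      group_by(.data$protein) %>%
      mutate(
        .log = log(.data$relative_level),
        .s = sd(.data$.log[is.finite(.data$.log)]),
        .noise = if (target_r < 1) {
          rnorm(n(), 0, .data$.s * sqrt(1 / target_r^2 - 1))
        } else 0,
        concentration = exp(log(scale_ngml) + .data$.log + .data$.noise)
      ) %>%
      ungroup() %>%
      select("sample_id", "protein", "concentration")
  })
}

#' Write a simulated dataset to disk
#'
#' Writes the sample metadata as TSV and the transition table as a
#' Skyline-export-style CSV.
#'
#' @param cohort Result of [generate_cohort()].
#' @param transitions Result of [generate_transition_data()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(cohort, transitions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta_path <- file.path(dir, "sample_meta.tsv")
  trans_path <- file.path(dir, "transition_report.csv")
  readr::write_tsv(cohort$meta, meta_path)
  readr::write_csv(transitions$transitions, trans_path)
  invisible(c(meta = meta_path, transitions = trans_path))
}

#' Read a Skyline-style transition report
#'
#' @param path CSV with columns `sample_id`, `replicate`, `batch`,
#'   `protein`, `peptide`, `transition_id`, `area_light`, `area_heavy`
#'   and optionally `area_external_standard`.
#' @return A tibble of transition records.
#' @export
read_transition_report <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read a sample metadata table
#' @param path TSV written by [write_simulation()] (or of the same layout).
#' @return A tibble of sample metadata.
#' @export
read_sample_meta <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
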
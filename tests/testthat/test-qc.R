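# minimal quant-shaped tibble for filter unit tests
fake_quant <- function(protein, peptide, sample_id, relative_level,
                       replicate_cv = NA_real_) {
  tibble::tibble(
    protein = protein, peptide = peptide, sample_id = sample_id,
    signature_transition = paste0(peptide, ".t01"),
    relative_level = relative_level, replicate_cv = replicate_cv,
    n_replicates = 3L,
    below_detection = FALSE,
    missing_quant = !is.finite(relative_level)
  )
}

test_that("cv_filter thresholds the median replicate CV", {
  q <- dplyr::bind_rows(
    fake_quant("A", "A_1", c("S1", "S2", "S3"), 1,
               replicate_cv = c(0.05, 0.08, 0.06)),
    fake_quant("B", "B_1", c("S1", "S2", "S3"), 1,
               replicate_cv = c(0.12, 0.15, 0.30)),
    fake_quant("C", "C_1", c("S1", "S2", "S3"), 1,
               replicate_cv = NA_real_)
  )
  out <- cv_filter(q, threshold = 0.10)
  expect_equal(out$status[out$peptide == "A_1"], "pass")
  expect_equal(out$status[out$peptide == "B_1"], "fail")
  expect_equal(out$median_cv[out$peptide == "B_1"], 0.15)
  expect_equal(out$status[out$peptide == "C_1"], "unevaluable")
})

test_that("range_filter uses the open reference interval", {
  q <- dplyr::bind_rows(
    fake_quant("IN", "IN_1", c("S1", "S2", "S3"), c(0.5, 1, 2)),
    fake_quant("LO", "LO_1", c("S1", "S2", "S3"), c(0.01, 0.02, 0.03)),
    fake_quant("HI", "HI_1", c("S1", "S2", "S3"), c(20, 30, 40)),
    fake_quant("EDGE", "EDGE_1", c("S1", "S2", "S3"), 0.1)
  )
  out <- range_filter(q)
  s <- setNames(out$status, out$peptide)
  expect_equal(unname(s[c("IN_1", "LO_1", "HI_1")]),
               c("pass", "fail", "fail"))
  # boundary value of the open interval fails
  expect_equal(unname(s["EDGE_1"]), "fail")
})

# hand-built interference: two transitions, deterministic areas; t1 gets
# an additive light-only bias in every sample
interfered_transitions <- function(bias = 400) {
  tidyr::expand_grid(sample_id = paste0("S", 1:6), replicate = 1:3,
                     transition_id = c("t1", "t2")) |>
    dplyr::mutate(
      protein = "P", peptide = "P_1",
      area_heavy = ifelse(transition_id == "t1", 600, 400),
      area_light = 2 * area_heavy + ifelse(transition_id == "t1", bias, 0)
    )
}

test_that("audit_flag flags the interfered transition, not its sibling", {
  flags <- audit_flag(interfered_transitions())$per_transition
  expect_true(flags$interfered[flags$transition_id == "t1"])
  expect_false(flags$interfered[flags$transition_id == "t2"])
  # without bias nothing is flagged
  clean <- audit_flag(interfered_transitions(bias = 0))$per_transition
  expect_false(any(clean$interfered))
})

test_that("single-transition peptides are unevaluable for interference", {
  tr <- interfered_transitions() |> dplyr::filter(transition_id == "t1")
  flags <- audit_flag(tr)$per_transition
  expect_false(any(flags$evaluable))
  q <- quantify_transitions(tr)
  out <- audit_filter(tr, q)
  expect_equal(out$status, "unevaluable")
})

test_that("audit_filter fails a peptide whose signature transition is hit", {
  tr <- interfered_transitions()
  q <- quantify_transitions(tr)   # t1 has the larger light area
  expect_equal(unique(q$signature_transition), "t1")
  out <- audit_filter(tr, q)
  expect_equal(out$status, "fail")
  # after excluding the interfered pair, the peptide passes on t2
  q2 <- quantify_transitions(
    tr, exclude_transitions = tibble::tibble(peptide = "P_1",
                                             transition_id = "t1"))
  out2 <- audit_filter(tr, q2)
  expect_equal(out2$status, "pass")
})

test_that("confounder_filter catches a planted batch effect", {
  withr::with_seed(77, {
    n <- 120
    meta <- tibble::tibble(
      sample_id = sprintf("S%03d", 1:n), group = "NL",
      center = rep(c("A", "B"), each = n / 2),
      batch = rep(sprintf("B%02d", 1:4), length.out = n)
    )
    shift <- ifelse(as.integer(sub("B", "", meta$batch)) %% 2 == 0,
                    log(2), 0)
    q <- dplyr::bind_rows(
      fake_quant("BAT", "BAT_1", meta$sample_id,
                 rlnorm(n, shift, 0.3)),
      fake_quant("OK", "OK_1", meta$sample_id, rlnorm(n, 0, 0.3))
    )
    out <- confounder_filter(q, meta)
    expect_equal(out$status[out$peptide == "BAT_1"], "fail")
    expect_equal(out$status[out$peptide == "OK_1"], "pass")
    expect_lt(out$p_batch[out$peptide == "BAT_1"], 0.05)
  })
})

test_that("single_marker_screen gates on the oriented NL-vs-PDAC AUC", {
  withr::with_seed(78, {
    n <- 200
    meta <- tibble::tibble(
      sample_id = sprintf("S%03d", 1:n),
      group = rep(c("PDAC", "NL"), each = n / 2)
    )
    is_case <- meta$group == "PDAC"
    q <- dplyr::bind_rows(
      fake_quant("UP", "UP_1", meta$sample_id, rlnorm(n, 1.5 * is_case, 0.4)),
      fake_quant("DOWN", "DOWN_1", meta$sample_id,
                 rlnorm(n, -1.5 * is_case, 0.4)),
      fake_quant("NULL0", "NULL0_1", meta$sample_id, rlnorm(n, 0, 0.4))
    )
    out <- single_marker_screen(q, meta)
    s <- setNames(out$status, out$peptide)
    expect_equal(unname(s[c("UP_1", "DOWN_1")]), c("pass", "pass"))
    expect_equal(unname(s["NULL0_1"]), "fail")
    expect_equal(out$direction[out$peptide == "DOWN_1"], "down")
    # oriented AUC never below 0.5
    expect_true(all(out$auc_nl_pdac >= 0.5))
  })
})

test_that("run_qc combines rules and is marker-order independent", {
  cfg <- cohort_config(
    group_sizes = tibble::tibble(
      group = c("PDAC", "NL"), center = c("A", "A"), n = c(50L, 50L),
      ca199_median = c(120, 7.4), ca199_mad = c(300, 3.6)),
    marker_specs = dplyr::bind_rows(
      marker_spec("LRG1", "up", target_auc = 0.9),
      marker_spec("LOW", "null", base_meanlog = log(0.01)),
      marker_spec("DEC01", "null")),
    interference_rate = 0, seed = 610)
  cohort <- generate_cohort(cfg)
  sim <- generate_transition_data(cohort$meta, cfg)
  q <- quantify_transitions(sim$transitions)
  qc <- run_qc(q, sim$transitions, cohort$meta)
  expect_equal(qc$range[qc$protein == "LOW"], "fail")
  expect_equal(qc$auc_screen[qc$protein == "LRG1"], "pass")
  expect_true("LRG1" %in% qc_survivors(qc))
  expect_false("LOW" %in% qc_survivors(qc))
  expect_equal(qc$passed, lengths(qc$failed_rules) == 0)

  # shuffling input row order changes nothing
  perm <- withr::with_seed(1, sample(nrow(q)))
  qc2 <- run_qc(q[perm, ], sim$transitions, cohort$meta)
  expect_equal(dplyr::arrange(qc2, protein)[, c("protein", "passed")],
               dplyr::arrange(qc, protein)[, c("protein", "passed")])

  dir <- withr::local_tempdir()
  path <- write_qc_report(qc, dir)
  expect_true(file.exists(path))
})
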
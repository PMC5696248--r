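test_that("enumerate_panels counts and orders candidates deterministically", {
  m25 <- c("CA19_9", sprintf("M%02d", 1:25))
  out <- enumerate_panels(m25, "CA19_9", min_size = 3, max_size = 3)
  expect_equal(nrow(out), choose(25, 2))
  expect_true(all(vapply(out$markers, `[`, character(1), 1) == "CA19_9"))

  one <- enumerate_panels(m25, "CA19_9", 1, 1)
  expect_equal(one$panel_id, "CA19_9")

  small <- enumerate_panels(c("A", "B", "C", "X"), "X", 1, 4)
  expect_equal(nrow(small), 8)
  expect_equal(small$panel_id,
               c("X", "X+A", "X+B", "X+C", "X+A+B", "X+A+C", "X+B+C",
                 "X+A+B+C"))
  # input order of the marker list does not matter
  shuffled <- enumerate_panels(c("C", "X", "A", "B"), "X", 1, 4)
  expect_identical(small$panel_id, shuffled$panel_id)

  expect_error(enumerate_panels(c("A", "X"), "X", 1, 5), "max_size")
  expect_error(enumerate_panels(c("A", "B"), "X", 1, 2), "anchor")
})

test_that("train_panel separates a linearly separable toy problem", {
  dat <- tibble::tibble(
    sample_id = as.character(1:8),
    is_case = rep(c(TRUE, FALSE), each = 4),
    m1 = c(10, 11, 12, 13, 1, 1.2, 1.4, 1.6),
    m2 = c(9, 10, 11, 12, 1, 1.1, 1.3, 1.5)
  )
  m <- train_panel(dat, c("m1", "m2"), spec_target = 0.9)
  pred <- predict(m, dat, type = "class")
  expect_equal(pred, dat$is_case)
  expect_equal(roc_auc(predict(m, dat), dat$is_case), 1)
  expect_equal(m$n_dropped, 0)
})

test_that("train_panel rejects duplicate markers and degenerate labels", {
  dat <- tibble::tibble(sample_id = as.character(1:6),
                        is_case = rep(c(TRUE, FALSE), 3),
                        m1 = rlnorm(6), m2 = rlnorm(6))
  expect_error(train_panel(dat, c("m1", "m1")), "distinct")
  one_class <- dplyr::mutate(dat, is_case = TRUE)
  expect_error(train_panel(one_class, c("m1", "m2")), "single class")
  expect_error(train_panel(dat, c("m1", "nope")), "nope")
})

test_that("decision scores are case-oriented even for inverted markers", {
  withr::with_seed(31, {
    n <- 200
    dat <- tibble::tibble(
      sample_id = as.character(1:n),
      is_case = rep(c(TRUE, FALSE), each = n / 2),
      down = rlnorm(n, -1.2 * rep(c(1, 0), each = n / 2), 0.5)
    )
    m <- train_panel(dat, "down")
    expect_gt(roc_auc(predict(m, dat), dat$is_case), 0.8)
  })
})

test_that("panel models serialize and reload bit-stably", {
  withr::with_seed(32, {
    n <- 120
    dat <- tibble::tibble(
      sample_id = as.character(1:n),
      is_case = rep(c(TRUE, FALSE), n / 2),
      m1 = rlnorm(n, 0.8 * rep(c(1, 0), n / 2), 0.5),
      m2 = rlnorm(n, 0, 0.5)
    )
    m <- train_panel(dat, c("m1", "m2"))
    path <- withr::local_tempfile(fileext = ".json")
    write_panel_model(m, path)
    m2 <- read_panel_model(path)
    expect_identical(predict(m, dat), predict(m2, dat))
    expect_identical(m$cutoff, m2$cutoff)
    expect_identical(unname(m$w), unname(m2$w))
  })
})

test_that("predict returns NA for rows with unusable marker values", {
  dat <- tibble::tibble(sample_id = as.character(1:6),
                        is_case = rep(c(TRUE, FALSE), 3),
                        m1 = c(2, 3, 4, 0.5, 0.6, 0.7))
  m <- train_panel(dat, "m1")
  new <- tibble::tibble(m1 = c(1, NA, 0))
  p <- predict(m, new)
  expect_false(is.na(p[1]))
  expect_true(all(is.na(p[2:3])))   # NA and log(0) rows
})

test_that("cv_folds stratifies exactly and reproducibly", {
  labels <- rep(c(TRUE, FALSE), c(60, 40))
  f1 <- cv_folds(labels, 5, seed = 9)
  f2 <- cv_folds(labels, 5, seed = 9)
  expect_identical(f1, f2)
  tab <- table(labels, f1)
  expect_true(all(tab["TRUE", ] == 12))
  expect_true(all(tab["FALSE", ] == 8))
  expect_error(cv_folds(rep(c(TRUE, FALSE), c(3, 97)), 5),
               "minority")
})

test_that("permuted labels give a null cross-validated AUC", {
  withr::with_seed(33, {
    n <- 200
    dat <- tibble::tibble(
      sample_id = as.character(1:n),
      is_case = sample(rep(c(TRUE, FALSE), each = n / 2)),
      m1 = rlnorm(n, 0, 0.5), m2 = rlnorm(n, 0, 0.5)
    )
    cv <- cross_validate_panel(dat, c("m1", "m2"), seed = 33)
    expect_gt(cv$auc, 0.5 - 0.08)
    expect_lt(cv$auc, 0.5 + 0.08)
  })
})

test_that("a planted strong panel beats each constituent marker in CV", {
  withr::with_seed(34, {
    n <- 300
    is_case <- rep(c(TRUE, FALSE), each = n / 2)
    d <- effect_for_auc(0.78, 0.5)
    dat <- tibble::tibble(
      sample_id = as.character(1:n), is_case = is_case,
      m1 = rlnorm(n, d * is_case, 0.5),
      m2 = rlnorm(n, -d * is_case, 0.5)
    )
    cv_panel <- cross_validate_panel(dat, c("m1", "m2"), seed = 34)
    cv_m1 <- cross_validate_panel(dat, "m1", seed = 34)
    cv_m2 <- cross_validate_panel(dat, "m2", seed = 34)
    expect_gt(cv_panel$auc, cv_m1$auc)
    expect_gt(cv_panel$auc, cv_m2$auc)
  })
})

test_that("panel_search applies the two-stage rule with a paired design", {
  dat <- make_recovery_cohort(91, n_cases = 150, n_controls = 150,
                              auc_marker = 0.78, n_decoys = 3)
  markers <- c("ca199", "LRG1", "TTR", sprintf("DEC%02d", 1:3))
  res <- panel_search(dat, markers, anchor = "ca199", min_size = 2,
                      max_size = 3, seed = 91)
  expect_equal(nrow(res), 5 + choose(5, 2))
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_true(all(res$survived_stage2[res$selected]))
  expect_true(all(!res$survived_stage1 | res$auc_gain >= 0.07))
  # the planted pair is the top-ranked panel
  expect_equal(res$panel_id[1], "ca199+LRG1+TTR")
  sel <- select_panels(res)
  expect_true(all(sel$selected))

  # column/marker order invariance of the ranked list
  res2 <- panel_search(dat[, c(1, 2, 7, 6, 5, 4, 3, 8)], rev(markers),
                       anchor = "ca199", min_size = 2, max_size = 3,
                       seed = 91)
  expect_identical(res$panel_id, res2$panel_id)
  expect_equal(res$cv_auc, res2$cv_auc)
})

test_that("anchor-only panels cannot survive stage 1", {
  dat <- make_recovery_cohort(92, n_cases = 100, n_controls = 100,
                              n_decoys = 2)
  res <- panel_search(dat, c("ca199", "DEC01", "DEC02"), anchor = "ca199",
                      min_size = 1, max_size = 2, seed = 92)
  anchor_row <- res[res$panel_id == "ca199", ]
  expect_equal(anchor_row$auc_gain, 0)
  expect_false(anchor_row$survived_stage1)
})

test_that("rows incomplete for any searched marker are dropped once", {
  dat <- make_recovery_cohort(93, n_cases = 60, n_controls = 60,
                              n_decoys = 2)
  dat$LRG1[1] <- NA
  dat$DEC01[2] <- 0
  res <- panel_search(dat, c("ca199", "LRG1", "DEC01"), anchor = "ca199",
                      min_size = 2, max_size = 3, seed = 93)
  expect_equal(attr(res, "n_dropped"), 2L)
})
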
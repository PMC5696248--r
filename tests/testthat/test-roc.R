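test_that("roc_auc matches exhaustive pair counting", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  s <- c(1, 3, 5, 2, 4)
  l <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(s, l), oracle_auc(s, l))
  # ties count one half
  s2 <- c(1, 2, 2, 2, 3)
  l2 <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_auc(s2, l2), oracle_auc(s2, l2))
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "cases and controls")
})

test_that("AUC is invariant under monotone transforms and negation", {
  withr::with_seed(21, {
    s <- rnorm(60)
    l <- rep(c(TRUE, FALSE), 30)
    a <- roc_auc(s, l)
    expect_equal(roc_auc(exp(s), l), a)
    expect_equal(roc_auc(5 * s - 2, l), a)
    expect_equal(roc_auc(-s, l), 1 - a)
  })
})

test_that("delong_test matches the double-loop oracle to 1e-12", {
  instances <- list(
    list(a = c(0.9, 0.8, 0.35, 0.7, 0.2, 0.4, 0.6, 0.1, 0.5, 0.3),
         b = c(0.7, 0.6, 0.5, 0.9, 0.1, 0.3, 0.2, 0.4, 0.8, 0.35),
         l = rep(c(TRUE, FALSE), each = 5)),
    list(a = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8),
         b = c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8, 4, 5),
         l = rep(c(TRUE, FALSE), 6)),
    # ties present in both score vectors
    list(a = c(1, 2, 2, 3, 2, 1, 2, 3, 1, 1, 2, 2, 3, 1),
         b = c(2, 2, 1, 3, 3, 1, 1, 2, 2, 3, 1, 2, 1, 3),
         l = rep(c(TRUE, FALSE), c(6, 8)))
  )
  for (ins in instances) {
    got <- delong_test(ins$a, ins$b, ins$l)
    ref <- oracle_delong(ins$a, ins$b, ins$l)
    expect_equal(got$auc_a, ref$auc_a, tolerance = 1e-12)
    expect_equal(got$auc_b, ref$auc_b, tolerance = 1e-12)
    expect_equal(got$var_diff, ref$var_diff, tolerance = 1e-12)
    expect_equal(got$p_value, ref$p, tolerance = 1e-12)
  }
})

test_that("delong_test is symmetric and flags degeneracy", {
  withr::with_seed(22, {
    a <- rnorm(80); b <- rnorm(80)
    l <- rep(c(TRUE, FALSE), 40)
    ab <- delong_test(a, b, l)
    ba <- delong_test(b, a, l)
    expect_equal(ab$z, -ba$z)
    expect_equal(ab$p_value, ba$p_value)
    same <- delong_test(a, a, l)
    expect_true(same$degenerate)
    expect_equal(same$p_value, 1)
  })
})

test_that("tidy methods return one-row tibbles", {
  withr::with_seed(23, {
    a <- rnorm(40); b <- rnorm(40)
    l <- rep(c(TRUE, FALSE), 20)
    td <- tidy(delong_test(a, b, l))
    expect_s3_class(td, "tbl_df")
    expect_equal(nrow(td), 1)
    tm <- tidy(mcnemar_test(a > 0, b > 0, l))
    expect_equal(nrow(tm), 1)
    expect_true(all(c("b", "c", "p.value") %in% names(tm)))
  })
})

test_that("cutoff selection reproduces order-statistic examples", {
  scores <- 1:20
  labels <- rep(c(FALSE, TRUE), each = 10)
  out <- sensitivity_at_specificity(scores, labels, 0.9)
  expect_equal(out$cutoff, 9.5)
  expect_equal(out$specificity, 0.9)
  expect_equal(out$sensitivity, 1)
  # perfect specificity: cutoff above the control maximum
  out1 <- sensitivity_at_specificity(scores, labels, 1)
  expect_equal(out1$specificity, 1)
  expect_gt(out1$cutoff, 10)
})

test_that("cutoff with ties matches the exhaustive scan oracle", {
  scores <- c(1, 2, 2, 2, 3, 4, 2, 3, 4, 5)
  labels <- rep(c(FALSE, TRUE), each = 5)
  for (target in c(0.6, 0.8, 0.9)) {
    got <- sensitivity_at_specificity(scores, labels, target)
    expect_equal(got$cutoff, oracle_cutoff(scores, labels, target))
    expect_gte(got$specificity, target)
  }
})

test_that("apply_cutoff counts sensitivity and specificity", {
  scores <- c(5, 6, 7, 1, 2, 3, 4, 8)
  labels <- rep(c(TRUE, FALSE), each = 4)
  out <- apply_cutoff(scores, labels, 4.5)
  expect_equal(out$sensitivity, 0.75)
  expect_equal(out$specificity, 0.75)
  expect_equal(out$predictions, scores >= 4.5)
})

test_that("mcnemar_test matches hand-computed exact and flagged cases", {
  pred_a <- rep(TRUE, 10)
  pred_b <- rep(FALSE, 10)
  labels <- rep(TRUE, 10)
  out <- mcnemar_test(pred_a, pred_b, labels, scope = "cases")
  expect_equal(out$b, 10)
  expect_equal(out$c, 0)
  expect_equal(out$p_value, 2 * 0.5^10)
  expect_equal(out$method, "exact")

  # b = 15, c = 5 by construction
  pa <- rep(c(TRUE, FALSE, TRUE), c(15, 5, 10))
  pb <- rep(c(FALSE, TRUE, TRUE), c(15, 5, 10))
  lab <- rep(TRUE, 30)
  out2 <- mcnemar_test(pa, pb, lab, scope = "cases")
  expect_equal(c(out2$b, out2$c), c(15, 5))
  expect_equal(out2$p_value, oracle_mcnemar_exact(15, 5))

  same <- mcnemar_test(pa, pa, lab, scope = "cases")
  expect_true(same$no_discordance)
  expect_equal(same$p_value, 1)
})

test_that("mcnemar_test switches to continuity-corrected chi-squared", {
  pa <- rep(c(TRUE, FALSE), c(20, 10))
  pb <- rep(c(FALSE, TRUE), c(20, 10))
  lab <- rep(TRUE, 30)
  out <- mcnemar_test(pa, pb, lab, scope = "cases")
  expect_equal(out$method, "chisq")
  expect_equal(out$p_value,
               pchisq((abs(20 - 10) - 1)^2 / 30, 1, lower.tail = FALSE))
  # matches base R's continuity-corrected McNemar on the 2x2 table
  ref <- stats::mcnemar.test(matrix(c(0, 20, 10, 0), 2), correct = TRUE)
  expect_equal(out$p_value, unname(ref$p.value))
})

test_that("cases-only scope ignores control samples", {
  pa <- c(TRUE, FALSE, TRUE, TRUE)
  pb <- c(FALSE, FALSE, TRUE, FALSE)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  out <- mcnemar_test(pa, pb, lab, scope = "cases")
  expect_equal(c(out$b, out$c), c(1, 0))
})

test_that("ppv evaluates the printed formula and its edge cases", {
  expect_equal(ppv(1, 1, 0.1), 1)
  expect_equal(ppv(0.5, 0.5, 0.5), 0.5)
  p <- 12.9e-5
  expect_equal(ppv(0.825, 0.944),
               0.825 * p / (0.825 * p + (1 - 0.944) * (1 - p)))
  expect_warning(out <- ppv(0, 1, 0), "Zero PPV denominator")
  expect_equal(out, 0)
})

test_that("roc_curve starts at (0,0), ends at (1,1), integrates to AUC", {
  withr::with_seed(24, {
    s <- rnorm(50)
    l <- rep(c(TRUE, FALSE), 25)
    rc <- roc_curve(s, l)
    expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
    expect_equal(c(rc$fpr[nrow(rc)], rc$tpr[nrow(rc)]), c(1, 1))
    trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2)
    expect_equal(trap, roc_auc(s, l), tolerance = 1e-12)
  })
})
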
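#' Panel selection criteria
#'
#' The two-stage selection rule applied to anchored candidate panels:
#' stage 1 keeps panels whose cross-validated AUC beats the anchor's by at
#' least `min_auc_gain` with a significant DeLong test; stage 2
#' additionally requires a sensitivity gain strictly greater than
#' `min_sens_gain` at the fixed-specificity cutoff with a significant
#' McNemar test (cases-only scope).
#'
#' @param min_auc_gain Minimum AUC improvement over the anchor (`>=`).
#' @param delong_alpha Two-sided DeLong significance level.
#' @param min_sens_gain Minimum sensitivity improvement (`>`, strictly).
#' @param mcnemar_alpha McNemar significance level.
#' @param spec_target Specificity at which sensitivities are compared.
#' @param cv_folds Number of stratified cross-validation folds.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(min_auc_gain = 0.07, delong_alpha = 0.05,
                               min_sens_gain = 0.10, mcnemar_alpha = 0.05,
                               spec_target = 0.90, cv_folds = 5L) {
  .assert_positive(min_auc_gain, "min_auc_gain", strict = FALSE)
  .assert_positive(min_sens_gain, "min_sens_gain", strict = FALSE)
  .assert_fraction(delong_alpha, "delong_alpha")
  .assert_fraction(mcnemar_alpha, "mcnemar_alpha")
  .assert_fraction(spec_target, "spec_target")
  if (cv_folds < 2) abort("`cv_folds` must be at least 2.")
  structure(
    list(min_auc_gain = min_auc_gain, delong_alpha = delong_alpha,
         min_sens_gain = min_sens_gain, mcnemar_alpha = mcnemar_alpha,
         spec_target = spec_target, cv_folds = as.integer(cv_folds)),
    class = "selection_criteria"
  )
}

#' Enumerate anchored marker panels
#'
#' All marker subsets that contain the anchor, with total size between
#' `min_size` and `max_size`, in deterministic order (by size, then
#' lexicographically over the sorted non-anchor markers). The candidate
#' count is `sum over k of choose(m - 1, k - 1)` for `m` markers.
#'
#' @param markers Available marker identifiers (must include `anchor`).
#' @param anchor Anchor marker present in every panel.
#' @param min_size,max_size Panel size range (anchor included).
#' @return A tibble: `panel_id`, `markers` (list-column, anchor first),
#'   `size`.
#' @export
#' @examples
#' nrow(enumerate_panels(c("CA19_9", "A", "B", "C"), "CA19_9", 3, 3))
enumerate_panels <- function(markers, anchor, min_size = 1,
                             max_size = 3) {
  markers <- unique(as.character(markers))
  if (!anchor %in% markers) abort("`anchor` must be among `markers`.")
  if (max_size > length(markers)) {
    abort("`max_size` exceeds the number of available markers.")
  }
  if (min_size < 1 || min_size > max_size) {
    abort("Need 1 <= min_size <= max_size.")
  }
  others <- sort(setdiff(markers, anchor))
  rows <- purrr::map(seq(min_size, max_size), function(k) {
    if (k == 1) return(list(anchor))
    combos <- utils::combn(others, k - 1, simplify = FALSE)
    purrr::map(combos, ~ c(anchor, .x))
  })
  panels <- purrr::flatten(rows)
  tibble(
    panel_id = purrr::map_chr(panels, paste, collapse = "+"),
    markers = panels,
    size = lengths(panels)
  )
}

# linear / radial kernel decision values from stored parameters
.decision_values <- function(model, newx) {
  x <- sweep(sweep(as.matrix(newx), 2, model$center), 2, model$scale, "/")
  raw <- if (model$kernel == "linear") {
    drop(x %*% model$w) - model$rho
  } else {
    k <- exp(-model$gamma *
               (outer(rowSums(x^2), rowSums(model$sv^2), "+") -
                  2 * x %*% t(model$sv)))
    drop(k %*% model$coefs) - model$rho
  }
  raw * model$sign
}

#' Train an SVM panel classifier
#'
#' Fits a two-class support vector machine on the panel markers:
#' marker values are log-transformed (plasma analyte levels are
#' log-normal), standardized with training-set constants, and passed to a
#' C-classification SVM (linear kernel, cost 1 by default — the dual
#' decision function `sum(alpha_i y_i K(x, x_i)) + b` with no tuning
#' loop). The continuous decision value is retained and oriented so that
#' higher means more case-like; the sign function is applied only at the
#' frozen cutoff stage. Rows with missing panel markers are dropped and
#' counted. The frozen decision cutoff is set on the training decision
#' values at `spec_target` specificity.
#'
#' @param data Tibble with `sample_id`, the marker columns, and a logical
#'   case indicator column.
#' @param markers Panel marker column names (no duplicates).
#' @param response Name of the logical case column (default `"is_case"`).
#' @param cost SVM regularization constant.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param spec_target Training specificity at which the decision cutoff is
#'   frozen.
#' @param log_transform Log-transform marker values before standardizing.
#' @param seed Integer seed recorded in the model metadata.
#' @return An object of class `panel_model`.
#' @export
train_panel <- function(data, markers, response = "is_case", cost = 1,
                        kernel = c("linear", "radial"), spec_target = 0.9,
                        log_transform = TRUE, seed = 1L) {
  kernel <- match.arg(kernel)
  if (anyDuplicated(markers)) abort("Panel markers must be distinct.")
  missing_cols <- setdiff(c(markers, response), names(data))
  if (length(missing_cols) > 0) {
    abort(paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(data[, markers, drop = FALSE])
  if (log_transform) x <- log(x)
  keep <- rowSums(!is.finite(x)) == 0 & !is.na(data[[response]])
  n_dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  y <- data[[response]][keep]
  if (length(unique(y)) < 2) {
    abort(sprintf("Panel [%s]: a single class remains after dropping %d rows.",
                  paste(markers, collapse = "+"), n_dropped))
  }
  center <- colMeans(x)
  scale_ <- sqrt(colSums(sweep(x, 2, center)^2) / max(1, nrow(x) - 1))
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  yf <- factor(ifelse(y, "case", "control"), levels = c("control", "case"))
  fit <- .with_seed(seed, {
    e1071::svm(xs, yf, kernel = kernel, cost = cost, scale = FALSE)
  })
  model <- list(
    markers = markers, response = response, kernel = kernel, cost = cost,
    log_transform = log_transform, center = center, scale = scale_,
    sv = unname(as.matrix(fit$SV)), coefs = drop(unname(fit$coefs)),
    rho = fit$rho, gamma = fit$gamma, sign = 1,
    n_train = nrow(xs), n_dropped = n_dropped, seed = as.integer(seed)
  )
  if (kernel == "linear") {
    model$w <- drop(t(model$sv) %*% model$coefs)
  }
  # orient decision values so cases score higher (computed on the
  # standardized training matrix directly)
  class(model) <- "panel_model"
  raw <- if (kernel == "linear") drop(xs %*% model$w) - model$rho else {
    k <- exp(-model$gamma *
               (outer(rowSums(xs^2), rowSums(model$sv^2), "+") -
                  2 * xs %*% t(model$sv)))
    drop(k %*% model$coefs) - model$rho
  }
  if (roc_auc(raw, y) < 0.5) model$sign <- -1
  train_scores <- raw * model$sign
  cut <- sensitivity_at_specificity(train_scores, y, spec_target)
  model$cutoff <- cut$cutoff
  model$train_specificity <- cut$specificity
  model$train_sensitivity <- cut$sensitivity
  model$spec_target <- spec_target
  model
}

#' @export
print.panel_model <- function(x, ...) {
  cat("<panel_model>", paste(x$markers, collapse = " + "), "\n")
  cat(sprintf("  %s kernel, cost %.3g, %d training samples (%d dropped)\n",
              x$kernel, x$cost, x$n_train, x$n_dropped))
  cat(sprintf("  frozen cutoff %.4f (training spec %.3f, sens %.3f)\n",
              x$cutoff, x$train_specificity, x$train_sensitivity))
  invisible(x)
}

#' Decision scores of a trained panel
#'
#' Continuous case-oriented decision values of a [train_panel()] model on
#' new samples; with `type = "class"`, the frozen-cutoff binary call.
#'
#' @param object A `panel_model`.
#' @param newdata Tibble containing the panel's marker columns.
#' @param type `"score"` (default) or `"class"`.
#' @param ... Unused.
#' @return Numeric scores or a logical predicted-case vector (NA for rows
#'   with missing markers).
#' @export
predict.panel_model <- function(object, newdata, type = c("score", "class"),
                                ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[, object$markers, drop = FALSE])
  if (object$log_transform) x <- log(x)
  ok <- rowSums(!is.finite(x)) == 0
  scores <- rep(NA_real_, nrow(x))
  if (any(ok)) scores[ok] <- .decision_values(object, x[ok, , drop = FALSE])
  if (type == "score") scores else scores >= object$cutoff
}

#' @export
tidy.panel_model <- function(x, ...) {
  if (x$kernel == "linear") {
    tibble(term = c(x$markers, "(rho)"),
           estimate = c(x$w * x$sign, x$rho * x$sign),
           center = c(x$center, NA), scale = c(x$scale, NA))
  } else {
    tibble(term = x$markers, center = x$center, scale = x$scale)
  }
}

#' @export
glance.panel_model <- function(x, ...) {
  tibble(markers = paste(x$markers, collapse = "+"), kernel = x$kernel,
         cost = x$cost, n_train = x$n_train, n_dropped = x$n_dropped,
         cutoff = x$cutoff, train_specificity = x$train_specificity,
         train_sensitivity = x$train_sensitivity, seed = x$seed)
}

#' Stratified cross-validation folds
#'
#' Deterministic (seeded) fold assignment stratified by class and,
#' when provided, center.
#'
#' @param labels Logical case labels.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @param strata Optional extra stratification factor (e.g. center).
#' @return Integer fold assignment per sample.
#' @export
cv_folds <- function(labels, folds = 5L, seed = 1L, strata = NULL) {
  if (folds > min(table(labels))) {
    abort("Fold count exceeds the minority-class size.")
  }
  key <- if (is.null(strata)) as.character(labels) else {
    paste(labels, strata)
  }
  fold <- integer(length(labels))
  .with_seed(seed, {
    for (k in unique(key)) {
      idx <- which(key == k)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

#' Cross-validated decision scores of a panel
#'
#' Stratified k-fold cross-validation: the SVM (including the
#' standardization constants, recomputed per training fold so no test-fold
#' information leaks) is fit on each training fold and scored on the held
#' out fold; the out-of-fold decision values are concatenated into one
#' cross-validated score vector.
#'
#' @param data Tibble with marker columns and the case column.
#' @param markers Panel marker names.
#' @param response Logical case column name.
#' @param criteria A [selection_criteria()] (supplies the fold count).
#' @param seed Integer seed for the fold assignment.
#' @param strata Optional stratification factor aligned with `data` rows.
#' @param ... Passed to [train_panel()].
#' @return A list: `scores` (out-of-fold, aligned with `data` rows),
#'   `labels`, `fold`, `auc`.
#' @export
cross_validate_panel <- function(data, markers, response = "is_case",
                                 criteria = selection_criteria(),
                                 seed = 1L, strata = NULL, ...) {
  labels <- data[[response]]
  fold <- cv_folds(labels, criteria$cv_folds, seed, strata)
  scores <- rep(NA_real_, nrow(data))
  for (f in seq_len(criteria$cv_folds)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    m <- train_panel(train, markers, response, seed = seed, ...)
    scores[fold == f] <- predict(m, test)
  }
  ok <- !is.na(scores)
  list(scores = scores, labels = labels, fold = fold,
       auc = roc_auc(scores[ok], labels[ok]))
}

#' Anchored combinatorial panel search
#'
#' Enumerates all anchored panels in the given size range, cross-validates
#' an SVM for each, and applies the two-stage selection rule against the
#' anchor alone: stage 1 requires an AUC gain of at least `min_auc_gain`
#' with DeLong p below `delong_alpha` (paired, on the cross-validated
#' scores); stage 2 requires a sensitivity gain strictly above
#' `min_sens_gain` at the `spec_target` cutoff with McNemar p below
#' `mcnemar_alpha` (cases-only). All candidates are evaluated on the
#' samples complete for every searched marker, so the paired tests are
#' valid; the dropped-row count is recorded as an attribute. Survivors are
#' ranked by cross-validated AUC, then sensitivity gain, then marker
#' names.
#'
#' @param data Tibble with `sample_id`, marker columns, and the case
#'   column.
#' @param markers Markers to search over (including the anchor).
#' @param anchor Anchor marker identifier.
#' @param min_size,max_size Panel size bounds (anchor included).
#' @param criteria A [selection_criteria()].
#' @param response Logical case column name.
#' @param seed Integer seed (folds are shared across candidates, keeping
#'   comparisons paired).
#' @param strata Optional stratification factor for the folds.
#' @param ... Passed to [train_panel()].
#' @return A tibble, one row per candidate: `panel_id`, `markers`, `size`,
#'   `cv_auc`, `auc_gain`, `delong_p`, `sensitivity`, `sens_gain`,
#'   `mcnemar_p`, `survived_stage1`, `survived_stage2`, `selected`,
#'   `rank`; the anchor's own cross-validation is stored in the
#'   `anchor_cv` attribute.
#' @export
panel_search <- function(data, markers, anchor = "CA19_9", min_size = 2,
                         max_size = 3, criteria = selection_criteria(),
                         response = "is_case", seed = 1L, strata = NULL,
                         ...) {
  markers <- unique(markers)
  x <- as.matrix(data[, markers, drop = FALSE])
  complete <- rowSums(!is.finite(x) | x <= 0) == 0 &
    !is.na(data[[response]])
  n_dropped <- sum(!complete)
  df <- data[complete, , drop = FALSE]
  if (!is.null(strata)) strata <- strata[complete]

  cands <- enumerate_panels(markers, anchor, min_size, max_size)
  anchor_cv <- cross_validate_panel(df, anchor, response, criteria, seed,
                                    strata, ...)
  anchor_cut <- sensitivity_at_specificity(anchor_cv$scores,
                                           anchor_cv$labels,
                                           criteria$spec_target)
  anchor_pred <- anchor_cv$scores >= anchor_cut$cutoff

  eval_one <- function(mk) {
    cv <- cross_validate_panel(df, mk, response, criteria, seed, strata, ...)
    dl <- delong_test(cv$scores, anchor_cv$scores, cv$labels)
    cut <- sensitivity_at_specificity(cv$scores, cv$labels,
                                      criteria$spec_target)
    pred <- cv$scores >= cut$cutoff
    mc <- mcnemar_test(pred, anchor_pred, cv$labels, scope = "cases")
    tibble(
      cv_auc = cv$auc, auc_gain = cv$auc - anchor_cv$auc,
      delong_p = dl$p_value,
      sensitivity = cut$sensitivity, specificity = cut$specificity,
      sens_gain = cut$sensitivity - anchor_cut$sensitivity,
      mcnemar_p = mc$p_value
    )
  }

  res <- bind_rows(purrr::map(cands$markers, eval_one))
  out <- dplyr::bind_cols(cands, res) %>%
    mutate(
      survived_stage1 = .data$auc_gain >= criteria$min_auc_gain &
        .data$delong_p < criteria$delong_alpha,
      survived_stage2 = .data$survived_stage1 &
        .data$sens_gain > criteria$min_sens_gain &
        .data$mcnemar_p < criteria$mcnemar_alpha,
      selected = .data$survived_stage2
    ) %>%
    arrange(dplyr::desc(.data$cv_auc), dplyr::desc(.data$sens_gain),
            .data$panel_id) %>%
    mutate(rank = dplyr::row_number())
  attr(out, "anchor_cv") <- c(anchor_cv[c("auc")],
                              anchor_cut[c("cutoff", "sensitivity",
                                           "specificity")])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Select surviving panels from search results
#'
#' Filters a [panel_search()] result to the panels surviving both stages,
#' keeping the deterministic ranking.
#'
#' @param results A [panel_search()] tibble.
#' @return The surviving subset (possibly empty, never an error).
#' @export
select_panels <- function(results) {
  results %>% filter(.data$selected) %>%
    arrange(.data$rank)
}

#' Serialize a panel model as text
#'
#' Writes every parameter needed to reproduce the decision function
#' bit-for-bit (support vectors, coefficients, bias, standardization
#' constants, orientation, frozen cutoff, seed) as JSON at full precision.
#'
#' @param model A `panel_model`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_panel_model <- function(model, path) {
  payload <- unclass(model)
  payload$sv <- as.data.frame(payload$sv)
  # digits = I(17): 17 significant digits round-trip any double exactly,
  # whereas digits = NA prints ~15 and can perturb reloaded weights
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Restore a serialized panel model
#' @param path JSON written by [write_panel_model()].
#' @return A `panel_model`.
#' @export
read_panel_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$sv <- as.matrix(p$sv)
  dimnames(p$sv) <- NULL
  p$center <- unlist(p$center)
  p$scale <- unlist(p$scale)
  if (!is.null(p$w)) p$w <- unlist(p$w)
  structure(p, class = "panel_model")
}
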
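#' Rank features by one-way ANOVA F statistic
#'
#' Vectorized between-group over within-group mean-square ratio per feature.
#' Constant features get `F = 0`; perfect separators (zero within-group
#' variance with non-zero between-group variance) get `F = Inf` and rank
#' first. Ties are broken lexicographically by feature id.
#'
#' @param m Feature-by-sample matrix.
#' @param labels A `subtype_result` (or tibble with `sample_id`, `subtype`)
#'   covering the matrix samples.
#' @param top_k Number of features to keep (default 100).
#' @return A tibble of the `top_k` features, ranked: `feature`, `f_stat`,
#'   `rank`.
#' @export
anova_f_rank <- function(m, labels, top_k = 100) {
  check_omics_matrix(m)
  check_scalar_num(top_k, "top_k", lower = 1, integer = TRUE)
  lab <- labels_for_samples(labels, colnames(m))
  groups <- split(seq_along(lab), lab)
  if (length(groups) < 2L) abort("need at least two classes")
  if (any(lengths(groups) < 2L)) {
    abort(sprintf("class '%s' has fewer than 2 samples",
                  names(groups)[lengths(groups) < 2L][1L]))
  }
  n <- ncol(m); k <- length(groups)
  grand <- rowMeans(m)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    mg <- rowMeans(m[, g, drop = FALSE])
    ssb <- ssb + length(g) * (mg - grand)^2
    ssw <- ssw + rowSums((m[, g, drop = FALSE] - mg)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msb == 0, 0, ifelse(msw == 0, Inf, msb / msw))
  ord <- order(-f, rownames(m))
  top <- head(ord, top_k)
  tibble(feature = rownames(m)[top], f_stat = unname(f[top]),
         rank = seq_along(top))
}

labels_for_samples <- function(labels, sample_ids) {
  if (!all(c("sample_id", "subtype") %in% names(labels))) {
    abort("`labels` needs columns sample_id and subtype")
  }
  idx <- match(sample_ids, labels$sample_id)
  if (anyNA(idx)) abort("some matrix samples have no subtype label")
  droplevels(factor(labels$subtype[idx]))
}

# Samples-by-features design matrix from per-omic selections.
build_design <- function(omics, selections) {
  blocks <- purrr::imap(omics, function(m, tag) {
    feats <- selections[[tag]]$feature
    t(m[feats, , drop = FALSE])
  })
  do.call(cbind, blocks)
}

fit_svm <- function(design, y, svm_params) {
  params <- utils::modifyList(list(kernel = "radial", cost = 1, gamma = NULL,
                                   seed = 1), svm_params %||% list())
  gamma <- params$gamma %||% (1 / ncol(design))
  withr::with_seed(params$seed,
    e1071::svm(x = design, y = y, kernel = params$kernel, cost = params$cost,
               gamma = gamma, probability = TRUE, scale = TRUE))
}

#' Train a subtype label-transfer classifier
#'
#' Selects the top `top_k` features per omic by ANOVA F against the subtype
#' labels, concatenates the per-omic selections into one design matrix, and
#' fits a radial-basis SVM with probability outputs (`e1071::svm`).
#'
#' @param omics Named list of feature-by-sample matrices (e.g. `expr`,
#'   `meth`), sample-aligned.
#' @param labels A `subtype_result` for the training samples.
#' @param top_k Features kept per omic (default 100).
#' @param svm_params List overriding `kernel`, `cost`, `gamma`, `seed`.
#' @return A list of class `label_transfer_model` holding the per-omic
#'   selections, the fitted SVM, class levels, training accuracy, and the
#'   training data needed for common-feature refits.
#' @export
train_labeler <- function(omics, labels, top_k = 100, svm_params = list()) {
  if (!is.list(omics) || is.null(names(omics))) abort("`omics` must be a named list")
  purrr::walk(omics, check_omics_matrix)
  ids <- colnames(omics[[1L]])
  purrr::walk(omics, ~ if (!identical(colnames(.x), ids))
    abort("omics matrices must share an identical ordered sample set"))
  y <- labels_for_samples(labels, ids)
  if (nlevels(y) < 2L) abort("training labels contain a single class")
  selections <- purrr::map(omics, anova_f_rank, labels = labels, top_k = top_k)
  design <- build_design(omics, selections)
  fit <- fit_svm(design, y, svm_params)
  pred <- predict(fit, design)
  structure(list(selections = selections,
                 svm = fit,
                 svm_params = svm_params,
                 classes = levels(y),
                 training_accuracy = mean(pred == y),
                 train_omics = omics,
                 train_labels = tibble(sample_id = ids, subtype = y)),
            class = "label_transfer_model")
}

#' @export
print.label_transfer_model <- function(x, ...) {
  cat(sprintf("Subtype label-transfer SVM: classes [%s], %s features, training accuracy %.3f\n",
              paste(x$classes, collapse = ", "),
              paste(purrr::map_int(x$selections, nrow), collapse = "+"),
              x$training_accuracy))
  invisible(x)
}

#' Predict subtype labels for aligned omics matrices
#'
#' @param object A `label_transfer_model`.
#' @param omics Named list of feature-by-sample matrices containing the
#'   model's selected features.
#' @param ... Unused.
#' @return A tibble: `sample_id`, `subtype`, plus one probability column per
#'   class (`prob_G1`, ...).
#' @export
predict.label_transfer_model <- function(object, omics, ...) {
  purrr::walk(omics, check_omics_matrix)
  design <- build_design(omics, object$selections)
  pred <- predict(object$svm, design, probability = TRUE)
  probs <- attr(pred, "probabilities")[, object$classes, drop = FALSE]
  out <- tibble(sample_id = rownames(design),
                subtype = factor(as.character(pred), levels = object$classes))
  for (cl in object$classes) out[[paste0("prob_", cl)]] <- unname(probs[, cl])
  out
}

# Risk score and event probability used throughout: the predicted
# probability of the worst-prognosis class (last level).
poor_class_probability <- function(predictions, classes) {
  predictions[[paste0("prob_", classes[length(classes)])]]
}

#' Monte-Carlo cross-validation of the label-transfer classifier
#'
#' Ten (by default) seeded random 60/40 train/test splits. Within each
#' split, ANOVA-F feature selection and the SVM fit use the training 60%
#' only; the held-out 40% is scored with Harrell's C-index (risk = predicted
#' probability of the worst-prognosis class), the binary Brier score, and
#' the log-rank test between predicted subtypes. A split whose training
#' half lacks a class is redrawn (at most 100 attempts, logged).
#'
#' @param omics Named list of sample-aligned feature-by-sample matrices.
#' @param clinical Clinical tibble for the same samples.
#' @param labels A `subtype_result` for the same samples.
#' @param n_folds Number of random splits (default 10).
#' @param train_fraction Training fraction per split (default 0.6).
#' @param top_k Features per omic (default 100).
#' @param svm_params Passed to [train_labeler()].
#' @param seed Integer seed making the whole procedure reproducible.
#' @return A tibble of class `cv_report`, one row per fold: `fold`,
#'   `n_train`, `n_test`, `accuracy`, `c_index`, `brier`, `logrank_p`; the
#'   aggregate summary is available via [glance()] / [aggregate_folds()].
#' @export
crossvalidate <- function(omics, clinical, labels, n_folds = 10,
                          train_fraction = 0.6, top_k = 100,
                          svm_params = list(), seed = 1) {
  purrr::walk(omics, check_omics_matrix)
  check_clinical(clinical)
  check_scalar_num(n_folds, "n_folds", lower = 1, integer = TRUE)
  check_scalar_num(train_fraction, "train_fraction", lower = 0, upper = 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  ids <- colnames(omics[[1L]])
  check_aligned(ids, clinical)
  y_all <- labels_for_samples(labels, ids)
  n <- length(ids)
  n_train <- round(train_fraction * n)
  if (n_train < 2L || n - n_train < 2L) abort("not enough samples for the split")

  rows <- withr::with_seed(seed, purrr::map(seq_len(n_folds), function(f) {
    train_idx <- NULL
    for (attempt in seq_len(100L)) {
      cand <- sample.int(n, n_train)
      if (nlevels(droplevels(y_all[cand])) >= 2L &&
          nlevels(droplevels(y_all[-cand])) >= 1L) {
        train_idx <- cand
        if (attempt > 1L) inform(sprintf("fold %d: redrew split %d time(s)", f, attempt - 1L))
        break
      }
    }
    if (is.null(train_idx)) {
      abort(sprintf("fold %d: could not draw a split with both classes in training", f))
    }
    test_idx <- setdiff(seq_len(n), train_idx)
    tr_omics <- purrr::map(omics, ~ .x[, train_idx, drop = FALSE])
    te_omics <- purrr::map(omics, ~ .x[, test_idx, drop = FALSE])
    model <- train_labeler(tr_omics, labels, top_k = top_k, svm_params = svm_params)
    pred <- predict(model, te_omics)
    te_clin <- clinical[match(ids[test_idx], clinical$sample_id), ]
    risk <- poor_class_probability(pred, model$classes)
    preds_df <- tibble(sample_id = pred$sample_id, risk_score = risk,
                       event_probability = risk)
    ci <- tryCatch(concordance_index(preds_df, te_clin), error = function(e) NA_real_)
    br <- brier_score(preds_df, te_clin)
    lr <- tryCatch(logrank_test(pred, te_clin)$p_value, error = function(e) NA_real_)
    truth <- y_all[test_idx]
    tibble(fold = f, n_train = length(train_idx), n_test = length(test_idx),
           accuracy = mean(pred$subtype == truth),
           c_index = ci, brier = br, logrank_p = lr)
  }))
  out <- bind_rows(rows)
  class(out) <- c("cv_report", class(out))
  attr(out, "scheme") <- list(n_folds = n_folds, train_fraction = train_fraction,
                              top_k = top_k, seed = seed)
  out
}

#' @describeIn crossvalidate Aggregate summary across folds.
#' @param x,... Tidier arguments.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) aggregate_folds(x)

#' Transfer subtype labels to an external cohort via common features
#'
#' Intersects the model's selected features per omic with the features
#' available in the external cohort, refits the SVM on the training cohort
#' restricted to those common features (the default, mirroring two-cohort
#' transfer where probe sets differ), and predicts the external samples.
#'
#' @param model A `label_transfer_model` from [train_labeler()].
#' @param external Named list of external feature-by-sample matrices (names
#'   matching the training omics).
#' @param retrain_on_common Refit on the common features (default `TRUE`);
#'   `FALSE` requires the external cohort to carry every selected feature.
#' @return Prediction tibble as in [predict.label_transfer_model()], with a
#'   `"common_features"` attribute giving the per-omic counts used.
#' @export
predict_external <- function(model, external, retrain_on_common = TRUE) {
  if (!inherits(model, "label_transfer_model")) abort("`model` must be a label_transfer_model")
  if (!is.list(external) || is.null(names(external))) abort("`external` must be a named list")
  purrr::walk(external, check_omics_matrix)
  omic_tags <- intersect(names(model$selections), names(external))
  if (!length(omic_tags)) abort("external cohort shares no omic with the model")
  common <- purrr::map(setNames(omic_tags, omic_tags), function(tag) {
    intersect(model$selections[[tag]]$feature, rownames(external[[tag]]))
  })
  if (!sum(lengths(common))) {
    abort("no selected features are present in the external cohort",
          class = "aesurv_selection_error")
  }
  if (!retrain_on_common && any(lengths(common) <
                                purrr::map_int(model$selections[omic_tags], nrow))) {
    abort("external cohort is missing selected features; set retrain_on_common = TRUE")
  }
  restricted <- purrr::map(setNames(omic_tags, omic_tags), function(tag) {
    sel <- model$selections[[tag]]
    sel[sel$feature %in% common[[tag]], , drop = FALSE]
  })
  use_model <- model
  use_model$selections <- restricted
  if (retrain_on_common) {
    design <- build_design(model$train_omics[omic_tags], restricted)
    y <- labels_for_samples(model$train_labels, rownames(design))
    use_model$svm <- fit_svm(design, y, model$svm_params)
  }
  out <- predict(use_model, external[omic_tags])
  attr(out, "common_features") <- purrr::map_int(common, length)
  out
}
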
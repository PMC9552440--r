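test_that("anova_f_rank matches the classical F computation and edge cases", {
  m <- rbind(toy = c(1, 2, 3, 4, 5, 6),
             flat = rep(2, 6),
             perfect = c(0, 0, 0, 10, 10, 10))
  colnames(m) <- sprintf("s%d", 1:6)
  labels <- tibble::tibble(sample_id = colnames(m),
                           subtype = factor(rep(c("G1", "G2"), each = 3)))
  res <- anova_f_rank(m, labels, top_k = 3)
  # G1: 1,2,3; G2: 4,5,6 -> MSB = 13.5, MSW = 1, F = 13.5
  expect_equal(res$f_stat[res$feature == "toy"], 13.5)
  ref <- anova(lm(m["toy", ] ~ labels$subtype))
  expect_equal(res$f_stat[res$feature == "toy"], ref$`F value`[1], tolerance = 1e-12)
  expect_identical(res$feature[1], "perfect")
  expect_identical(res$f_stat[1], Inf)
  expect_identical(res$feature[3], "flat")
  expect_equal(res$f_stat[res$feature == "flat"], 0)

  bad <- tibble::tibble(sample_id = colnames(m),
                        subtype = factor(c("G1", rep("G2", 5))))
  expect_error(anova_f_rank(m, bad), "fewer than 2")
})

test_that("anova_f_rank breaks F ties lexicographically by feature id", {
  m <- rbind(zeta = c(1, 2, 10, 11), alpha = c(1, 2, 10, 11))
  colnames(m) <- sprintf("s%d", 1:4)
  labels <- tibble::tibble(sample_id = colnames(m),
                           subtype = factor(c("G1", "G1", "G2", "G2")))
  res <- anova_f_rank(m, labels, top_k = 2)
  expect_identical(res$feature, c("alpha", "zeta"))
})

test_that("train_labeler fits a separable cohort perfectly and deterministically", {
  cohort <- small_cohort(seed = 41, n = 100, informative = 40)
  labels <- true_label_tibble(cohort)
  omics <- list(expr = cohort$expr, meth = cohort$meth)
  model <- train_labeler(omics, labels, top_k = 30)
  expect_equal(model$training_accuracy, 1)

  pred1 <- predict(model, omics)
  model2 <- train_labeler(omics, labels, top_k = 30)
  expect_identical(predict(model2, omics), pred1)

  one_class <- labels
  one_class$subtype <- factor(rep("G1", nrow(labels)))
  expect_error(train_labeler(omics, one_class, top_k = 30), "single class")
})

test_that("permuted labels destroy cross-validated accuracy", {
  cohort <- small_cohort(seed = 43, n = 120, informative = 40)
  labels <- true_label_tibble(cohort)
  perm <- labels
  perm$subtype <- withr::with_seed(9, sample(perm$subtype))
  cv <- suppressMessages(
    crossvalidate(list(expr = cohort$expr, meth = cohort$meth),
                  cohort$clinical, perm, n_folds = 5, top_k = 30, seed = 2))
  expect_true(mean(cv$accuracy) > 0.3 && mean(cv$accuracy) < 0.75)
  expect_true(mean(cv$c_index, na.rm = TRUE) > 0.35 &&
                mean(cv$c_index, na.rm = TRUE) < 0.65)
})

test_that("crossvalidate honors the scheme and approaches the oracle C-index", {
  cohort <- generate_cohort(synthetic_config(n_samples = 300, effect_size = 2,
                                             hazard_ratio = 3, n_genes_expr = 400,
                                             n_cpg_meth = 400, seed = 13))
  labels <- true_label_tibble(cohort)
  cv <- crossvalidate(list(expr = cohort$expr, meth = cohort$meth),
                      cohort$clinical, labels, n_folds = 10, seed = 5)
  expect_identical(nrow(cv), 10L)
  expect_true(all(cv$n_train == round(0.6 * 300)))
  expect_true(all(cv$n_test == 300 - round(0.6 * 300)))
  expect_gt(mean(cv$accuracy), 0.95)

  # the subtype is the only prognostic signal: CV C-index should sit near the
  # oracle C of the true labels, which a binary risk score cannot exceed
  oracle_preds <- tibble::tibble(sample_id = cohort$clinical$sample_id,
                                 risk_score = as.numeric(cohort$true_labels == "G2"))
  oracle_c <- concordance_index(oracle_preds, cohort$clinical)
  expect_gt(mean(cv$c_index), oracle_c - 0.05)
  expect_gt(mean(cv$accuracy), 0.9)
  agg <- glance(cv)
  expect_lt(agg$logrank_p_geomean, 0.01)
})

test_that("fold feature selection is a pure function of the training fold", {
  cohort <- small_cohort(seed = 47, n = 80, informative = 20)
  labels <- true_label_tibble(cohort)
  train_ids <- cohort$clinical$sample_id[1:48]
  sel1 <- anova_f_rank(cohort$expr[, train_ids], labels, top_k = 20)
  # corrupt every sample OUTSIDE the training fold
  expr2 <- cohort$expr
  test_ids <- setdiff(colnames(expr2), train_ids)
  expr2[, test_ids] <- expr2[, test_ids] + 100
  sel2 <- anova_f_rank(expr2[, train_ids], labels, top_k = 20)
  expect_identical(sel1, sel2)
})

test_that("predict_external refits on common features and self-predicts consistently", {
  cohort <- small_cohort(seed = 51, n = 100, informative = 40)
  labels <- true_label_tibble(cohort)
  omics <- list(expr = cohort$expr, meth = cohort$meth)
  model <- train_labeler(omics, labels, top_k = 30)

  # 100% shared features + refit reproduces training-cohort predictions
  full <- predict_external(model, omics, retrain_on_common = TRUE)
  expect_identical(full$subtype, predict(model, omics)$subtype)
  expect_identical(unname(attr(full, "common_features")), c(30L, 30L))

  # missing features: runs and reports the reduced count
  drop_feats <- function(m, keep_frac, seed) {
    keep <- withr::with_seed(seed, sample(rownames(m), round(keep_frac * nrow(m))))
    m[keep, , drop = FALSE]
  }
  ext <- list(expr = drop_feats(cohort$expr, 0.9, 1),
              meth = drop_feats(cohort$meth, 0.9, 2))
  pred <- predict_external(model, ext)
  expect_true(all(attr(pred, "common_features") <= 30))
  acc <- mean(as.character(pred$subtype) == cohort$true_labels[pred$sample_id])
  expect_gt(acc, 0.9)

  none <- list(expr = `rownames<-`(cohort$expr, paste0("x_", rownames(cohort$expr))))
  expect_error(predict_external(model, none), class = "aesurv_selection_error")
})
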
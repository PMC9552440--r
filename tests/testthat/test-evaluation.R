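test_that("concordance_index matches closed-form toy cases", {
  clin <- tibble::tibble(sample_id = c("a", "b", "c"), time = c(1, 3, 5),
                         event = c(1, 1, 1))
  perfect <- tibble::tibble(sample_id = c("a", "b", "c"), risk_score = c(3, 2, 1))
  expect_equal(concordance_index(perfect, clin), 1)

  flat <- tibble::tibble(sample_id = c("a", "b", "c"), risk_score = c(1, 1, 1))
  expect_equal(concordance_index(flat, clin), 0.5)

  # censored four-subject case, value frozen from the brute-force oracle:
  # permissible pairs (1,2),(1,3),(1,4),(2,3),(2,4); concordant all but (2,3)
  clin4 <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                          time = c(2, 4, 6, 8), event = c(1, 1, 0, 1))
  preds4 <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                           risk_score = c(0.9, 0.3, 0.5, 0.1))
  expect_equal(oracle_concordance(clin4$time, clin4$event, preds4$risk_score), 0.8)
  expect_equal(concordance_index(preds4, clin4), 0.8)

  all_cens <- tibble::tibble(sample_id = c("a", "b"), time = c(1, 2),
                             event = c(0, 0))
  expect_error(concordance_index(tibble::tibble(sample_id = c("a", "b"),
                                                risk_score = c(1, 2)), all_cens),
               class = "aesurv_undefined_error")
})

test_that("concordance_index agrees with brute force and survival::concordance", {
  for (s in 1:25) {
    withr::with_seed(s, {
      n <- sample(5:30, 1)
      time <- round(rexp(n, 1 / 100), 1) + 0.5
      event <- rbinom(n, 1, 0.7)
      risk <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force risk ties
    })
    if (!any(event == 1)) next
    clin <- tibble::tibble(sample_id = sprintf("s%d", 1:n), time = time,
                           event = event)
    preds <- tibble::tibble(sample_id = sprintf("s%d", 1:n), risk_score = risk)
    mine <- tryCatch(concordance_index(preds, clin), error = function(e) NA_real_)
    orac <- oracle_concordance(time, event, risk)
    expect_equal(mine, orac, tolerance = 1e-12)
    if (!is.na(mine)) {
      ref <- survival::concordance(survival::Surv(time, event) ~ risk,
                                   reverse = TRUE)$concordance
      expect_equal(mine, unname(ref), tolerance = 1e-12)
    }
  }
})

test_that("brier_score evaluates probabilistic accuracy with optional horizon", {
  clin <- tibble::tibble(sample_id = c("a", "b"), time = c(100, 900),
                         event = c(1, 0))
  perfect <- tibble::tibble(sample_id = c("a", "b"), event_probability = c(1, 0))
  expect_equal(brier_score(perfect, clin), 0)

  half <- tibble::tibble(sample_id = c("a", "b"), event_probability = c(0.5, 0.5))
  expect_equal(brier_score(half, clin), 0.25)

  p <- tibble::tibble(sample_id = c("a", "b"), event_probability = c(0.8, 0.2))
  expect_equal(brier_score(p, clin), 0.04)

  expect_error(brier_score(tibble::tibble(sample_id = "a", event_probability = 1.2),
                           clin[1, ]), "\\[0, 1\\]")

  # horizon: early-censored subjects are ambiguous and dropped
  clin3 <- tibble::tibble(sample_id = c("a", "b", "c"),
                          time = c(100, 50, 900), event = c(1, 0, 0))
  p3 <- tibble::tibble(sample_id = c("a", "b", "c"),
                       event_probability = c(0.9, 0.5, 0.1))
  expect_equal(brier_score(p3, clin3, horizon = 200),
               ((0.9 - 1)^2 + (0.1 - 0)^2) / 2)
})

test_that("logrank_test matches the manual risk-table tally", {
  clin <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                         time = c(1, 2, 3, 4, 5, 6), event = rep(1, 6))
  labels <- tibble::tibble(sample_id = clin$sample_id,
                           subtype = factor(rep(c("G1", "G2"), each = 3)))
  res <- logrank_test(labels, clin)
  manual <- oracle_logrank(clin$time, clin$event, labels$subtype)
  expect_equal(res$statistic, manual, tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(manual, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # duplicated groups: statistic 0, p 1
  clin_dup <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
                             time = rep(c(5, 10, 15, 20), 2),
                             event = rep(c(1, 0, 1, 1), 2))
  lab_dup <- tibble::tibble(sample_id = clin_dup$sample_id,
                            subtype = factor(rep(c("G1", "G2"), each = 4)))
  res_dup <- logrank_test(lab_dup, clin_dup)
  expect_equal(res_dup$statistic, 0, tolerance = 1e-12)
  expect_equal(res_dup$p_value, 1, tolerance = 1e-12)
})

test_that("aggregate_folds uses sample SD and geometric-mean p", {
  folds <- tibble::tibble(c_index = c(0.9, 0.94), brier = c(0.1, 0.2),
                          logrank_p = c(1e-2, 1e-4))
  agg <- aggregate_folds(folds)
  expect_equal(agg$c_index_mean, 0.92)
  expect_equal(agg$c_index_sd, sqrt(((0.9 - 0.92)^2 + (0.94 - 0.92)^2) / 1))
  expect_equal(agg$logrank_p_geomean, 1e-3, tolerance = 1e-12)

  single <- aggregate_folds(folds[1, ])
  expect_equal(single$c_index_mean, 0.9)
  expect_equal(single$c_index_sd, 0)
})

test_that("covariate_tests picks the right test per covariate type", {
  clin <- tibble::tibble(
    sample_id = sprintf("s%d", 1:20),
    time = rep(c(100, 200), 10), event = rep(1, 20),
    age = rep(c(40, 41, 42, 43, 44), 4),
    gender = rep(c("f", "m"), each = 10),
    onecat = rep("same", 20))
  labels <- tibble::tibble(sample_id = clin$sample_id,
                           subtype = factor(rep(c("G1", "G2"), 10)))
  res <- covariate_tests(labels, clin)
  expect_identical(res$test[res$covariate == "age"], "wilcoxon")
  expect_identical(res$test[res$covariate == "gender"], "chi_square")
  expect_gt(res$p_value[res$covariate == "age"], 0.9)  # identical distributions
  expect_equal(res$statistic[res$covariate == "onecat"], 0)
  expect_equal(res$p_value[res$covariate == "onecat"], 1)

  # perfectly associated 2x2 table: chi-square = n = 20 without correction
  clin2 <- clin
  clin2$gender <- ifelse(labels$subtype == "G1", "f", "m")
  res2 <- covariate_tests(labels, clin2, covariates = "gender")
  expect_equal(res2$statistic, 20)
  expect_lt(res2$p_value, 0.001)

  clin3 <- clin
  clin3$age <- NA_real_
  expect_warning(covariate_tests(labels, clin3, covariates = "age"), "skipped")
})

test_that("cox_compare reports one in-sample C-index per covariate set", {
  cohort <- small_cohort(seed = 31, n = 200, genes = 30, cpgs = 30,
                         informative = 5, drivers = 0)
  labels <- true_label_tibble(cohort)
  labels$subtype <- factor(labels$subtype, levels = c("G1", "G2"))
  res <- cox_compare(cohort$clinical, labels,
                     covariate_sets = list(subtype_only = "subtype",
                                           with_noise = c("subtype", "age"),
                                           age_only = "age"))
  expect_identical(nrow(res), 3L)
  expect_gt(res$c_index[res$model == "subtype_only"], 0.6)
  # age carries little signal beyond its subtype association
  expect_lt(abs(res$c_index[res$model == "with_noise"] -
                  res$c_index[res$model == "subtype_only"]), 0.05)
})
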
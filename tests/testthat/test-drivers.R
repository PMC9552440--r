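test_that("find_driver_genes computes Spearman r exactly on toy data", {
  expr <- matrix(c(3, 2, 1, 1, 2, 3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  meth <- matrix(c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  labels <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                           subtype = factor(c("G1", "G1", "G2")))
  res <- suppressMessages(find_driver_genes(expr, meth, labels, p_threshold = 1))
  expect_equal(res$spearman_r[res$gene == "g1"], -1)
  expect_equal(res$spearman_r[res$gene == "g2"], 1)
})

test_that("driver thresholds are strict inequalities at the boundary", {
  # permutation of ranks with sum(d^2) = 26 gives Spearman r exactly -0.3
  meth_vals <- 1:5
  expr_vals <- c(2, 5, 3, 4, 1)
  expect_equal(cor(meth_vals, expr_vals, method = "spearman"), -0.3)
  expr <- matrix(expr_vals, 1, dimnames = list("g", sprintf("s%d", 1:5)))
  meth <- matrix(meth_vals / 10, 1, dimnames = list("g", sprintf("s%d", 1:5)))
  labels <- tibble::tibble(sample_id = sprintf("s%d", 1:5),
                           subtype = factor(c("G1", "G1", "G1", "G2", "G2")))
  # p_threshold = 1 makes the Wilcoxon condition vacuous: the r condition decides
  at_boundary <- suppressMessages(
    find_driver_genes(expr, meth, labels, r_threshold = -0.3, p_threshold = 1))
  expect_identical(as.character(at_boundary$direction), "none")
  below <- suppressMessages(
    find_driver_genes(expr, meth, labels, r_threshold = -0.29, p_threshold = 1))
  expect_false(as.character(below$direction) == "none")

  # r = -1 exactly is not below a threshold of -1
  perfect <- matrix(5:1, 1, dimnames = list("g", sprintf("s%d", 1:5)))
  res_p <- suppressMessages(
    find_driver_genes(perfect, meth, labels, r_threshold = -1, p_threshold = 1))
  expect_identical(as.character(res_p$direction), "none")
})

test_that("planted drivers are recovered with correct directions", {
  cohort <- generate_cohort(synthetic_config(n_samples = 300, n_genes_expr = 300,
                                             n_cpg_meth = 300, n_informative = 50,
                                             n_drivers = 40, driver_corr = -0.8,
                                             seed = 23))
  labels <- true_label_tibble(cohort)
  res <- suppressMessages(find_driver_genes(cohort$expr, cohort$meth, labels))
  flagged <- res$gene[res$direction != "none"]
  sens <- mean(cohort$true_driver_genes %in% flagged)
  expect_gte(sens, 0.9)

  # directions follow the construction: alternating hypo_up / hyper_down
  drv <- res[res$gene %in% cohort$true_driver_genes & res$direction != "none", ]
  hypo <- drv[drv$direction == "hypo_up", ]
  expect_true(all(hypo$mean_meth_G2 < hypo$mean_meth_G1))
  expect_true(all(hypo$mean_expr_G2 > hypo$mean_expr_G1))

  # genes with independent methylation and expression stay unflagged
  null_genes <- setdiff(res$gene, c(cohort$true_driver_genes,
                                    rownames(cohort$expr)[1:50]))
  fpr <- mean(null_genes %in% flagged)
  expect_lte(fpr, 0.05)
})

test_that("constant vectors are skipped with a warning, tiny cohorts error", {
  expr <- matrix(c(1, 1, 1, 1, 2, 3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("flat", "ok"), c("s1", "s2", "s3")))
  meth <- matrix(c(0.4, 0.5, 0.6, 0.6, 0.5, 0.4), nrow = 2, byrow = TRUE,
                 dimnames = list(c("flat", "ok"), c("s1", "s2", "s3")))
  labels <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                           subtype = factor(c("G1", "G1", "G2")))
  expect_warning(res <- suppressMessages(find_driver_genes(expr, meth, labels)),
                 "constant")
  expect_identical(res$gene, "ok")

  expect_error(suppressMessages(
    find_driver_genes(expr[, 1:2], meth[, 1:2], labels[1:2, ])), "fewer than 3")
})

test_that("hypergeometric enrichment matches the exact tail and boundary cases", {
  universe <- sprintf("g%02d", 1:20)
  query <- universe[1:10]
  sets <- list(hit = universe[1:5], none = universe[11:15])
  res <- hypergeom_enrichment(query, sets, universe)
  # overlap 5 of a 5-gene set: p = C(15,5)/C(20,10)
  expect_equal(res$p_value[res$set_name == "hit"],
               choose(15, 5) / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p_value[res$set_name == "hit"],
               oracle_hypergeom_tail(5, 5, 20, 10), tolerance = 1e-12)
  expect_equal(res$p_value[res$set_name == "none"],
               oracle_hypergeom_tail(0, 5, 20, 10), tolerance = 1e-12)

  # query = universe: saturation, p = 1 for every set
  res_sat <- hypergeom_enrichment(universe, sets, universe)
  expect_true(all(res_sat$p_value == 1))
  expect_true(all(res_sat$overlap == res_sat$set_size))

  expect_error(hypergeom_enrichment(query, sets, character(0)), "non-empty")
  expect_error(hypergeom_enrichment(c(query, "zz"), sets, universe), "subset")
})

test_that("BH adjustment is monotone and order-preserving", {
  withr::with_seed(31, {
    universe <- sprintf("g%03d", 1:200)
    query <- sample(universe, 40)
    sets <- lapply(1:15, function(i) sample(universe, sample(5:30, 1)))
    names(sets) <- sprintf("set%02d", 1:15)
  })
  res <- hypergeom_enrichment(query, sets, universe)
  expect_true(all(res$adjusted_p >= res$p_value - 1e-15))
  expect_true(all(diff(res$p_value) >= -1e-15))   # sorted by raw p
  expect_true(all(diff(res$adjusted_p) >= -1e-15))  # BH keeps the order
  expect_true(all(res$adjusted_p <= 1))
})

test_that("GMT collections round-trip through read/write", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  attr(sets$alpha, "description") <- "first set"
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(names(back), c("alpha", "beta"))
  expect_identical(as.character(back$alpha), c("g1", "g2", "g3"))
  expect_identical(attr(back$alpha, "description"), "first set")

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("lonely_set", bad)
  expect_error(read_gmt(bad), "malformed")
})
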
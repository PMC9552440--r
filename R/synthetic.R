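#' Configuration for the synthetic multi-omics cohort generator
#'
#' Builds and validates the parameter set describing a simulated glioma-like
#' cohort: two latent subtypes with differing hazard, a block of informative
#' features per omic, planted methylation-driven genes with negative
#' methylation-expression coupling, and right-censored survival.
#'
#' @param n_samples Number of patients.
#' @param n_genes_expr Number of expression features (genes).
#' @param n_cpg_meth Number of methylation features. Methylation features are
#'   gene-level summaries and share the `gene_*` id namespace with expression,
#'   so the first `min(n_genes_expr, n_cpg_meth)` ids occur in both omics.
#' @param n_informative Number of subtype-informative features per omic.
#' @param subtype_proportion Fraction of samples in the better-prognosis
#'   subtype G1.
#' @param effect_size Mean shift (in within-subtype SD units) of informative
#'   features between subtypes.
#' @param hazard_ratio Hazard of subtype G2 relative to G1.
#' @param baseline_scale Mean event time (days) in subtype G1 under the
#'   exponential baseline hazard.
#' @param censor_rate Target fraction of censored subjects; the rate of the
#'   independent exponential censoring distribution is solved numerically to
#'   reach it in expectation.
#' @param n_drivers Number of planted methylation-driven genes (present in
#'   both omics, coupled through a shared latent factor).
#' @param driver_corr Target Spearman correlation between methylation and
#'   expression for planted driver genes, in `[-1, 0]`.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#'
#' @return A validated list of class `synthetic_config`.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_samples = 400,
                             n_genes_expr = 1000,
                             n_cpg_meth = 1000,
                             n_informative = 100,
                             subtype_proportion = 0.6,
                             effect_size = 2,
                             hazard_ratio = 3,
                             baseline_scale = 1000,
                             censor_rate = 0.3,
                             n_drivers = 50,
                             driver_corr = -0.8,
                             seed = 1) {
  check_scalar_num(n_samples, "n_samples", lower = 4, integer = TRUE)
  check_scalar_num(n_genes_expr, "n_genes_expr", lower = 1, integer = TRUE)
  check_scalar_num(n_cpg_meth, "n_cpg_meth", lower = 1, integer = TRUE)
  check_scalar_num(n_informative, "n_informative", lower = 0, integer = TRUE)
  check_scalar_num(subtype_proportion, "subtype_proportion",
                   lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_num(effect_size, "effect_size")
  check_scalar_num(hazard_ratio, "hazard_ratio", lower = 0, strict_lower = TRUE)
  check_scalar_num(baseline_scale, "baseline_scale", lower = 0, strict_lower = TRUE)
  check_scalar_num(censor_rate, "censor_rate", lower = 0, upper = 1,
                   strict_upper = TRUE)
  check_scalar_num(n_drivers, "n_drivers", lower = 0, integer = TRUE)
  check_scalar_num(driver_corr, "driver_corr", lower = -1, upper = 0)
  check_scalar_num(seed, "seed", integer = TRUE)
  if (n_informative > min(n_genes_expr, n_cpg_meth)) {
    stop_config("n_informative", "cannot exceed the width of either omic")
  }
  if (n_drivers > min(n_genes_expr, n_cpg_meth)) {
    stop_config("n_drivers", "cannot exceed min(n_genes_expr, n_cpg_meth)")
  }
  if (n_informative + n_drivers > min(n_genes_expr, n_cpg_meth)) {
    stop_config("n_drivers",
                "informative and driver blocks together exceed the matrix width")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes_expr = as.integer(n_genes_expr),
                 n_cpg_meth = as.integer(n_cpg_meth),
                 n_informative = as.integer(n_informative),
                 subtype_proportion = subtype_proportion,
                 effect_size = effect_size,
                 hazard_ratio = hazard_ratio,
                 baseline_scale = baseline_scale,
                 censor_rate = censor_rate,
                 n_drivers = as.integer(n_drivers),
                 driver_corr = driver_corr,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Exponential censoring rate c with P(C < T) = target when T is exponential
# with per-subject rates lambda: mean_i c/(c + lambda_i) = target.
solve_censor_rate <- function(lambda, target) {
  if (target <= 0) return(0)
  f <- function(cr) mean(cr / (cr + lambda)) - target
  stats::uniroot(f, lower = 1e-12, upper = 1e6 * max(lambda),
                 tol = 1e-12)$root
}

# Pearson rho giving the requested Spearman rho for bivariate Gaussian pairs.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a synthetic multi-omics survival cohort
#'
#' Draws a cohort under the statistical structure the subtyping pipeline
#' assumes: two subtypes whose informative features differ by a fixed mean
#' shift, proportional-hazards survival (exponential baseline, hazard
#' multiplied by `hazard_ratio` in G2), independent exponential censoring
#' tuned to the target censoring fraction, and planted driver genes whose
#' gene-level methylation and expression share a latent factor with opposite
#' signs, yielding the requested negative Spearman correlation.
#'
#' Methylation is generated on the logit scale and squashed through the
#' logistic function, so values lie strictly inside `(0, 1)`.
#'
#' @param config A [synthetic_config()] object.
#' @return A list of class `synthetic_cohort` with elements `expr` and `meth`
#'   (feature-by-sample matrices), `clinical` (tibble with `sample_id`,
#'   `time`, `event`, `age`, `gender`, `grade`, `tumor_type`, `idh_status`),
#'   `true_labels` (named character vector, `G1`/`G2`) and
#'   `true_driver_genes` (character vector of planted driver gene ids).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_samples = 60, n_genes_expr = 50,
#'                                            n_cpg_meth = 50, n_informative = 10,
#'                                            n_drivers = 5, seed = 7))
#' dim(cohort$expr)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  gene_ids_expr <- sprintf("gene_%05d", seq_len(cfg$n_genes_expr))
  gene_ids_meth <- sprintf("gene_%05d", seq_len(cfg$n_cpg_meth))

  n_g1 <- round(n * cfg$subtype_proportion)
  n_g1 <- min(max(n_g1, 2L), n - 2L)
  labels <- sample(c(rep("G1", n_g1), rep("G2", n - n_g1)))
  names(labels) <- sample_ids
  g2 <- labels == "G2"

  # Index layout shared by both omics: informative block, then driver block.
  idx_inf <- seq_len(cfg$n_informative)
  idx_drv <- cfg$n_informative + seq_len(cfg$n_drivers)

  # Expression: unit-variance Gaussian noise, subtype shift on informative
  # features with alternating sign (up/down regulated halves).
  expr <- matrix(rnorm(cfg$n_genes_expr * n), nrow = cfg$n_genes_expr,
                 dimnames = list(gene_ids_expr, sample_ids))
  if (cfg$n_informative > 0) {
    signs <- rep_len(c(1, -1), cfg$n_informative)
    expr[idx_inf, g2] <- expr[idx_inf, g2] + signs * cfg$effect_size
  }

  # Methylation on the logit scale around a per-feature baseline.
  base_logit <- rnorm(cfg$n_cpg_meth, mean = 0, sd = 0.5)
  meth_logit <- matrix(rnorm(cfg$n_cpg_meth * n, sd = 1),
                       nrow = cfg$n_cpg_meth,
                       dimnames = list(gene_ids_meth, sample_ids))
  meth_logit <- meth_logit + base_logit
  if (cfg$n_informative > 0) {
    signs_m <- rep_len(c(-1, 1), cfg$n_informative)
    meth_logit[idx_inf, g2] <- meth_logit[idx_inf, g2] + signs_m * cfg$effect_size
  }

  # Planted drivers: a latent factor u (subtype shift + noise) feeds
  # expression with positive sign and logit-methylation with negative sign;
  # the noise SD of the methylation channel is solved so the Spearman
  # correlation approaches driver_corr for Gaussian pairs.
  driver_genes <- character(0)
  if (cfg$n_drivers > 0) {
    rho_p <- abs(spearman_to_pearson(cfg$driver_corr))
    noise_sd <- if (rho_p >= 1) 0 else sqrt(1 / rho_p^2 - 1)
    drv_signs <- rep_len(c(1, -1), cfg$n_drivers)  # hypo_up then hyper_down
    for (j in seq_len(cfg$n_drivers)) {
      u <- drv_signs[j] * cfg$effect_size * g2 + rnorm(n)
      expr[idx_drv[j], ] <- u
      meth_logit[idx_drv[j], ] <- base_logit[idx_drv[j]] -
        (u + rnorm(n, sd = noise_sd))
    }
    driver_genes <- gene_ids_meth[idx_drv]
  }
  meth <- plogis(meth_logit)

  # Survival: exponential baseline, hazard scaled by hazard_ratio in G2.
  lambda <- (1 / cfg$baseline_scale) * ifelse(g2, cfg$hazard_ratio, 1)
  t_event <- rexp(n, rate = lambda)
  if (cfg$censor_rate > 0) {
    c_rate <- solve_censor_rate(lambda, cfg$censor_rate)
    t_cens <- rexp(n, rate = c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  # Clinical covariates, mildly associated with subtype for realism.
  age <- rnorm(n, mean = 50, sd = 12) + 5 * g2
  gender <- sample(c("female", "male"), n, replace = TRUE)
  grade_probs_g1 <- c(0.45, 0.40, 0.15)
  grade_probs_g2 <- c(0.15, 0.35, 0.50)
  grade <- vapply(g2, function(is_g2) {
    sample(c("II", "III", "IV"), 1L,
           prob = if (is_g2) grade_probs_g2 else grade_probs_g1)
  }, character(1))
  tumor_type <- ifelse(grade == "IV", "GBM", "LGG")
  idh_status <- vapply(g2, function(is_g2) {
    sample(c("mutant", "wildtype"), 1L,
           prob = if (is_g2) c(0.3, 0.7) else c(0.8, 0.2))
  }, character(1))

  clinical <- tibble(
    sample_id = sample_ids,
    time = time,
    event = event,
    age = age,
    gender = gender,
    grade = factor(grade, levels = c("II", "III", "IV"), ordered = TRUE),
    tumor_type = tumor_type,
    idh_status = idh_status
  )

  structure(list(expr = expr,
                 meth = meth,
                 clinical = clinical,
                 true_labels = labels,
                 true_driver_genes = driver_genes,
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic multi-omics cohort: %d samples, %d genes, %d methylation features\n",
              ncol(x$expr), nrow(x$expr), nrow(x$meth)))
  cat(sprintf("  subtypes: G1 = %d, G2 = %d; events = %d (%.0f%% censored)\n",
              sum(x$true_labels == "G1"), sum(x$true_labels == "G2"),
              sum(x$clinical$event),
              100 * mean(1 - x$clinical$event)))
  cat(sprintf("  planted driver genes: %d\n", length(x$true_driver_genes)))
  invisible(x)
}

#' Write a synthetic cohort to TSV files
#'
#' Emits `expr.tsv`, `meth.tsv` (features as rows, first column `feature_id`,
#' header row of sample ids), `clinical.tsv` and `truth.tsv` (per-sample true
#' labels plus the planted driver-gene list, for test use). Files round-trip
#' through [read_omics()] / [read_clinical()] and are byte-identical across
#' repeated writes of the same cohort.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param directory Output directory; created if missing.
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "synthetic_cohort")) abort("`cohort` must be a synthetic_cohort")
  if (!is.character(directory) || length(directory) != 1L || !nzchar(directory)) {
    abort("`directory` must be a non-empty path", class = "aesurv_path_error")
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory '%s'", directory),
                   class = "aesurv_path_error")
  }
  paths <- c(expr = file.path(directory, "expr.tsv"),
             meth = file.path(directory, "meth.tsv"),
             clinical = file.path(directory, "clinical.tsv"),
             truth = file.path(directory, "truth.tsv"))
  write_omics(cohort$expr, paths[["expr"]])
  write_omics(cohort$meth, paths[["meth"]])
  write_clinical(cohort$clinical, paths[["clinical"]])
  truth <- bind_rows(
    tibble(record = "label", id = names(cohort$true_labels),
           value = unname(cohort$true_labels)),
    tibble(record = "driver", id = cohort$true_driver_genes,
           value = "1")
  )
  readr::write_tsv(truth, paths[["truth"]])
  invisible(paths)
}
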
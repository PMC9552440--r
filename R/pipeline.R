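pipeline_stage_names <- c("simulate", "preprocess", "train_ae", "subtype",
                          "classify", "evaluate", "drivers")

default_pipeline_config <- function() {
  list(seed = 1L,
       out_dir = NULL,
       force = FALSE,
       simulate = list(),
       input = NULL,
       preprocess = list(mad_threshold = 0, scaler_mode = "robust",
                         epsilon = 0.001),
       autoencoder = list(epochs = 20, learning_rate = 1e-3, batch_size = 32,
                          dropout = 0.5, hidden = c(500, 100, 500)),
       subtype = list(alpha = 0.05, k_min = 2, k_max = 6),
       classify = list(top_k = 100, n_folds = 10, train_fraction = 0.6),
       drivers = list(r_threshold = -0.3, p_threshold = 0.05, gmt = NULL))
}

validate_pipeline_config <- function(config) {
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "aesurv_config_error")
  }
  merged <- utils::modifyList(defaults, config)
  if (is.null(merged$out_dir)) {
    abort("config is missing required key `out_dir`", class = "aesurv_config_error")
  }
  check_scalar_num(merged$seed, "seed", integer = TRUE)
  merged$seed <- as.integer(merged$seed)
  merged
}

stage_outputs <- function(out_dir) {
  list(simulate = file.path(out_dir, c("expr.tsv", "meth.tsv", "clinical.tsv")),
       preprocess = file.path(out_dir, "ae_input.tsv"),
       train_ae = file.path(out_dir, c("ae_model.rds", "ae_loss.tsv")),
       subtype = file.path(out_dir, c("subtypes.tsv", "screen.tsv", "selection.json")),
       classify = file.path(out_dir, "cv_report.tsv"),
       evaluate = file.path(out_dir, c("eval_report.json", "covariates.tsv")),
       drivers = file.path(out_dir, "drivers.tsv"))
}

#' Run the full subtyping pipeline from a configuration
#'
#' Executes the stages `simulate` (or load user-supplied inputs),
#' `preprocess`, `train_ae`, `subtype`, `classify`, `evaluate` and `drivers`
#' in order, each reading and writing only the documented TSV/JSON file
#' interfaces under `out_dir`. Stages whose outputs already exist are
#' skipped unless `force` is set. A reproducibility manifest (config
#' snapshot, per-stage seeds, MD5 digests of every stage output, package
#' version, timestamps) is written to `manifest.json` and returned.
#'
#' One global `seed` drives everything; each stage uses the deterministic
#' sub-seed `seed + stage index`, so a fixed global seed makes every stage
#' output byte-reproducible.
#'
#' @param config A YAML file path or a named list. Required key: `out_dir`.
#'   Optional blocks: `seed`, `force`, `simulate` (synthetic-cohort
#'   parameters) or `input` (paths `expr`, `meth`, `clinical`),
#'   `preprocess`, `autoencoder`, `subtype`, `classify`, `drivers`.
#' @return Invisibly, the manifest as a list of class `run_manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file not found: '%s'", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  cfg <- validate_pipeline_config(config)
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- stage_outputs(out_dir)
  stage_seed <- function(stage) cfg$seed + match(stage, pipeline_stage_names)
  cache_hits <- character(0)
  ran <- character(0)

  stage_due <- function(stage) {
    if (cfg$force || !all(file.exists(outputs[[stage]]))) return(TRUE)
    cache_hits <<- c(cache_hits, stage)
    inform(sprintf("stage %s: outputs present, skipped (use force to rerun)", stage))
    FALSE
  }

  # simulate / load -----------------------------------------------------
  if (!is.null(cfg$input)) {
    need <- c("expr", "meth", "clinical")
    miss <- setdiff(need, names(cfg$input))
    if (length(miss)) abort(sprintf("config `input` is missing: %s",
                                    paste(miss, collapse = ", ")))
    file.copy(unlist(cfg$input[need]), outputs$simulate, overwrite = TRUE)
    ran <- c(ran, "load")
  } else if (stage_due("simulate")) {
    sim_cfg <- do.call(synthetic_config,
                       utils::modifyList(list(seed = stage_seed("simulate")),
                                         cfg$simulate))
    cohort <- generate_cohort(sim_cfg)
    write_cohort(cohort, out_dir)
    ran <- c(ran, "simulate")
  }
  expr <- read_omics(outputs$simulate[1L])
  meth <- read_omics(outputs$simulate[2L])
  clinical <- read_clinical(outputs$simulate[3L])
  aligned <- align_samples(list(expr = expr, meth = meth), clinical)
  expr <- aligned$omics$expr; meth <- aligned$omics$meth
  clinical <- aligned$clinical

  # preprocess -----------------------------------------------------------
  if (stage_due("preprocess")) {
    X <- concat_preprocessed(expr, meth,
                             mad_threshold = cfg$preprocess$mad_threshold,
                             scaler_mode = cfg$preprocess$scaler_mode,
                             squash = TRUE, epsilon = cfg$preprocess$epsilon)
    write_omics(t(X), outputs$preprocess)
    ran <- c(ran, "preprocess")
  }
  X <- t(read_omics(outputs$preprocess))

  # train_ae -------------------------------------------------------------
  if (stage_due("train_ae")) {
    ae <- cfg$autoencoder
    ae_cfg <- autoencoder_config(input_dim = ncol(X), hidden = ae$hidden,
                                 learning_rate = ae$learning_rate,
                                 epochs = ae$epochs, batch_size = ae$batch_size,
                                 dropout = ae$dropout,
                                 seed = stage_seed("train_ae"))
    model <- train_autoencoder(X, ae_cfg)
    save_checkpoint(model, outputs$train_ae[1L])
    readr::write_tsv(tidy(model), outputs$train_ae[2L], progress = FALSE)
    ran <- c(ran, "train_ae")
  }
  model <- load_checkpoint(outputs$train_ae[1L])
  latent <- encode_samples(model, X)

  # subtype --------------------------------------------------------------
  if (stage_due("subtype")) {
    res <- discover_subtypes(latent, clinical, alpha = cfg$subtype$alpha,
                             k_min = cfg$subtype$k_min, k_max = cfg$subtype$k_max,
                             seed = stage_seed("subtype"))
    readr::write_tsv(as_tibble(res$subtypes), outputs$subtype[1L], progress = FALSE)
    readr::write_tsv(res$screen, outputs$subtype[2L], progress = FALSE)
    jsonlite::write_json(list(scores = res$selection$scores,
                              chosen_k = res$selection$chosen_k),
                         outputs$subtype[3L], auto_unbox = TRUE, digits = 10)
    ran <- c(ran, "subtype")
  }
  subtypes <- readr::read_tsv(outputs$subtype[1L], col_types = "cc",
                              progress = FALSE)
  subtypes$subtype <- factor(subtypes$subtype)
  class(subtypes) <- c("subtype_result", class(subtypes))

  # classify -------------------------------------------------------------
  if (stage_due("classify")) {
    cv <- crossvalidate(list(expr = expr, meth = meth), clinical, subtypes,
                        n_folds = cfg$classify$n_folds,
                        train_fraction = cfg$classify$train_fraction,
                        top_k = cfg$classify$top_k,
                        seed = stage_seed("classify"))
    readr::write_tsv(as_tibble(cv), outputs$classify, progress = FALSE)
    ran <- c(ran, "classify")
  }
  cv <- readr::read_tsv(outputs$classify, col_types = "iiidddd", progress = FALSE)

  # evaluate -------------------------------------------------------------
  if (stage_due("evaluate")) {
    agg <- aggregate_folds(cv)
    lr <- logrank_test(subtypes, clinical)
    cov_tests <- covariate_tests(subtypes, clinical)
    cov_sets <- list(subtype_only = "subtype")
    if (all(c("age", "gender", "grade", "tumor_type") %in% names(clinical))) {
      cov_sets$full <- c("age", "gender", "grade", "tumor_type", "subtype")
      cov_sets$tumor_type_only <- "tumor_type"
    }
    cox_cmp <- cox_compare(clinical, subtypes, cov_sets)
    jsonlite::write_json(list(cv_aggregate = agg, logrank = lr,
                              cox_models = cox_cmp),
                         outputs$evaluate[1L], auto_unbox = TRUE, digits = 10)
    readr::write_tsv(cov_tests, outputs$evaluate[2L], progress = FALSE)
    ran <- c(ran, "evaluate")
  }

  # drivers --------------------------------------------------------------
  if (stage_due("drivers")) {
    drv <- find_driver_genes(expr, meth, subtypes,
                             r_threshold = cfg$drivers$r_threshold,
                             p_threshold = cfg$drivers$p_threshold)
    readr::write_tsv(as_tibble(drv), outputs$drivers, progress = FALSE)
    if (!is.null(cfg$drivers$gmt)) {
      sets <- read_gmt(cfg$drivers$gmt)
      query <- drv$gene[drv$direction != "none"]
      enr <- hypergeom_enrichment(query, sets, universe = drv$gene)
      readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"),
                       progress = FALSE)
    }
    ran <- c(ran, "drivers")
  }

  all_files <- unique(unlist(outputs))
  all_files <- all_files[file.exists(all_files)]
  digests <- tools::md5sum(all_files)
  names(digests) <- basename(names(digests))
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("aesurv")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = cfg[setdiff(names(cfg), "force")],
    stage_seeds = setNames(cfg$seed + seq_along(pipeline_stage_names),
                           pipeline_stage_names),
    stages_run = ran,
    cache_hits = cache_hits,
    digests = as.list(digests)
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline manifest (aesurv %s, %s)\n", x$package_version, x$timestamp))
  cat(sprintf("  stages run: %s\n", paste(x$stages_run, collapse = ", ")))
  if (length(x$cache_hits)) {
    cat(sprintf("  cache hits: %s\n", paste(x$cache_hits, collapse = ", ")))
  }
  cat(sprintf("  %d output files digested\n", length(x$digests)))
  invisible(x)
}
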
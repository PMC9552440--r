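# Shared small fixtures, built in code at test time.

small_cohort <- function(seed = 7, n = 120, genes = 150, cpgs = 150,
                         informative = 40, drivers = 15, effect = 2, hr = 3) {
  generate_cohort(synthetic_config(
    n_samples = n, n_genes_expr = genes, n_cpg_meth = cpgs,
    n_informative = informative, n_drivers = drivers,
    effect_size = effect, hazard_ratio = hr, seed = seed))
}

true_label_tibble <- function(cohort) {
  tibble::tibble(sample_id = names(cohort$true_labels),
                 subtype = factor(cohort$true_labels))
}

tiny_ae_model <- function(seed = 1, d = 2, hidden = c(2, 1, 2)) {
  cfg <- autoencoder_config(input_dim = d, hidden = hidden, seed = seed,
                            l1_weight = 1e-3, l2_activity = 1e-2)
  withr::with_seed(seed, aesurv:::init_autoencoder(cfg))
}

random_survival <- function(n, seed, censor = 0.3) {
  withr::with_seed(seed, {
    time <- rexp(n, 1 / 500)
    cens <- if (censor > 0) rexp(n, censor / ((1 - censor) * 500)) else rep(Inf, n)
    tibble::tibble(sample_id = sprintf("S%03d", seq_len(n)),
                   time = pmin(time, cens),
                   event = as.integer(time <= cens))
  })
}

random_omics <- function(n_feat, n_samp, seed, prefix = "f") {
  withr::with_seed(seed, {
    matrix(rnorm(n_feat * n_samp), nrow = n_feat,
           dimnames = list(sprintf("%s%03d", prefix, seq_len(n_feat)),
                           sprintf("S%03d", seq_len(n_samp))))
  })
}
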
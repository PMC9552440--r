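#' Principal-component features for the baseline pipeline
#'
#' Mean-centered projection onto the top `n_components` principal components
#' (`stats::prcomp`), with each component's sign fixed so its
#' largest-magnitude loading is positive, making the transform fully
#' deterministic.
#'
#' @param data Samples-by-features matrix (sample rownames).
#' @param n_components Number of components (default 100, matching the
#'   autoencoder bottleneck width).
#' @return A list with `state` (class `pca_state`: `loadings`, `center`,
#'   `explained_variance` fractions) and `scores` (samples x components,
#'   columns `PC_001`, ...).
#' @export
pca_transform <- function(data, n_components = 100) {
  if (!is.matrix(data)) abort("`data` must be a samples-by-features matrix")
  check_scalar_num(n_components, "n_components", lower = 1, integer = TRUE)
  if (n_components > min(dim(data))) {
    abort(sprintf("n_components (%d) exceeds min(samples, features) = %d",
                  n_components, min(dim(data))), class = "aesurv_shape_error")
  }
  fit <- prcomp(data, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- fit$rotation
  scores <- fit$x
  # Sign convention: largest-magnitude loading positive.
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  colnames(scores) <- sprintf("PC_%03d", seq_len(ncol(scores)))
  rownames(scores) <- rownames(data)
  state <- structure(list(loadings = rot, center = fit$center,
                          explained_variance = expl[seq_len(ncol(rot))]),
                     class = "pca_state")
  list(state = state, scores = scores)
}

# Shared preprocessing front-end: per-omic MAD filter + robust scaling,
# optional unit-interval squash, then feature-wise concatenation with the
# samples as rows. Feature ids are prefixed per omic because gene-level
# methylation legitimately shares ids with expression.
concat_preprocessed <- function(expr, meth, mad_threshold = 0,
                                scaler_mode = "robust", squash = TRUE,
                                epsilon = 0.001) {
  pe <- preprocess_omics(expr, mad_threshold = mad_threshold,
                         scaler_mode = scaler_mode, squash = squash,
                         epsilon = epsilon)
  pm <- preprocess_omics(meth, mad_threshold = mad_threshold,
                         scaler_mode = scaler_mode, squash = squash,
                         epsilon = epsilon)
  a <- t(pe$train); colnames(a) <- paste0("expr:", colnames(a))
  b <- t(pm$train); colnames(b) <- paste0("meth:", colnames(b))
  cbind(a, b)
}

#' Autoencoder subtype-discovery pipeline
#'
#' The primary path end to end: per-omic preprocessing (MAD filter, robust
#' scaling, unit-interval squash), feature-wise concatenation, autoencoder
#' training, bottleneck extraction, univariate Cox screening, K-means with
#' cluster-number selection, and prognosis-ordered subtype naming.
#'
#' @param expr,meth Feature-by-sample matrices, sample-aligned with
#'   `clinical`.
#' @param clinical Clinical tibble.
#' @param alpha Cox-screen threshold.
#' @param k_min,k_max Candidate cluster numbers.
#' @param seed Global seed for training and clustering.
#' @param epochs,learning_rate,batch_size,dropout,hidden Autoencoder
#'   settings (see [autoencoder_config()]); pipeline defaults use the
#'   training-grade learning rate `1e-3` and 20 epochs.
#' @param mad_threshold,scaler_mode,epsilon Preprocessing settings.
#' @return A list of class `subtype_pipeline` (tag `"autoencoder"`):
#'   `subtypes`, `screen`, `selection`, `latent`, `model`.
#' @export
autoencoder_pipeline <- function(expr, meth, clinical, alpha = 0.05,
                                 k_min = 2, k_max = 6, seed = 1,
                                 epochs = 20, learning_rate = 1e-3,
                                 batch_size = 32, dropout = 0.5,
                                 hidden = c(500, 100, 500),
                                 mad_threshold = 0, scaler_mode = "robust",
                                 epsilon = 0.001) {
  aligned <- align_samples(list(expr = expr, meth = meth), clinical)
  X <- concat_preprocessed(aligned$omics$expr, aligned$omics$meth,
                           mad_threshold = mad_threshold,
                           scaler_mode = scaler_mode, squash = TRUE,
                           epsilon = epsilon)
  cfg <- autoencoder_config(input_dim = ncol(X), hidden = hidden,
                            learning_rate = learning_rate, epochs = epochs,
                            batch_size = batch_size, dropout = dropout,
                            seed = seed)
  model <- train_autoencoder(X, cfg)
  latent <- encode_samples(model, X)
  res <- discover_subtypes(latent, aligned$clinical, alpha = alpha,
                           k_min = k_min, k_max = k_max, seed = seed)
  structure(c(res, list(latent = latent, model = model, tag = "autoencoder")),
            class = "subtype_pipeline")
}

#' PCA baseline subtype-discovery pipeline
#'
#' Identical downstream machinery to [autoencoder_pipeline()] (Cox screen,
#' K-means selection, prognosis naming) with the 100 principal components in
#' place of the bottleneck features. Preprocessing is the same MAD filter
#' plus robust scaling, without the unit-interval squash (PCA needs no
#' bounded input). Degenerate clusterings (e.g. a singleton cluster) still
#' yield a subtype result; the classifier stage is where such labelings
#' fail, mirroring how a one-sample subtype cannot train an SVM.
#'
#' @inheritParams autoencoder_pipeline
#' @param n_components Number of principal components (default 100).
#' @return A list of class `subtype_pipeline` (tag `"pca"`): `subtypes`,
#'   `screen`, `selection`, `latent`, `state`.
#' @export
pca_pipeline <- function(expr, meth, clinical, alpha = 0.05, k_min = 2,
                         k_max = 6, seed = 1, n_components = 100,
                         mad_threshold = 0, scaler_mode = "robust") {
  aligned <- align_samples(list(expr = expr, meth = meth), clinical)
  X <- concat_preprocessed(aligned$omics$expr, aligned$omics$meth,
                           mad_threshold = mad_threshold,
                           scaler_mode = scaler_mode, squash = FALSE)
  n_components <- min(n_components, dim(X) - c(1L, 0L))
  pca <- pca_transform(X, n_components = n_components)
  res <- discover_subtypes(pca$scores, aligned$clinical, alpha = alpha,
                           k_min = k_min, k_max = k_max, seed = seed)
  structure(c(res, list(latent = pca$scores, state = pca$state, tag = "pca")),
            class = "subtype_pipeline")
}

#' @export
print.subtype_pipeline <- function(x, ...) {
  cat(sprintf("Subtype pipeline (%s): %d survival-associated features, chosen k = %d\n",
              x$tag, sum(x$screen$selected), x$selection$chosen_k))
  print(table(x$subtypes$subtype))
  invisible(x)
}

#' Adversarial cohort for the PCA-baseline contrast
#'
#' Generates a cohort whose dominant-variance directions are survival-
#' orthogonal. The expression omic carries many independent heavy-tailed
#' co-expression blocks (more blocks than retained principal components,
#' each block a shared t-distributed factor), none related to survival,
#' while the subtype separation lives in a modest-variance feature block
#' split across both omics. After robust scaling, variance-ranked top-k PCA
#' spends every component on the nuisance blocks; the autoencoder's bounded
#' (min-max squashed) input compresses the heavy tails instead, so
#' reconstruction learning retains the subtype signal in the bottleneck.
#'
#' @param n_samples Number of patients.
#' @param n_nuisance_factors Independent heavy-tailed expression factors
#'   (default 130; keep above the number of principal components retained
#'   downstream for the construction to bite).
#' @param features_per_factor Expression features loading on each factor.
#' @param n_signal Subtype-informative features per omic (default 30).
#' @param n_meth_noise Uninformative methylation features (default 30).
#' @param effect_size Subtype mean shift in SD units (default 1.5).
#' @param tail_df Degrees of freedom of the t-distributed nuisance factors;
#'   small values give the heavy tails the construction relies on.
#' @param hazard_ratio,baseline_scale,censor_rate Survival settings as in
#'   [synthetic_config()].
#' @param seed Integer seed.
#' @return A `synthetic_cohort` (without planted driver genes).
#' @export
adversarial_cohort <- function(n_samples = 300, n_nuisance_factors = 130,
                               features_per_factor = 8, n_signal = 30,
                               n_meth_noise = 30, effect_size = 1.5,
                               tail_df = 1.5, hazard_ratio = 3,
                               baseline_scale = 1000, censor_rate = 0.3,
                               seed = 1) {
  check_scalar_num(n_samples, "n_samples", lower = 10, integer = TRUE)
  check_scalar_num(seed, "seed", integer = TRUE)
  check_scalar_num(tail_df, "tail_df", lower = 0.5)
  withr::with_seed(seed, {
    n <- n_samples
    sample_ids <- sprintf("S%04d", seq_len(n))
    labels <- sample(c(rep("G1", round(0.55 * n)),
                       rep("G2", n - round(0.55 * n))))
    names(labels) <- sample_ids
    g2 <- labels == "G2"

    # Expression: subtype block + heavy-tailed survival-orthogonal blocks.
    nuisance <- do.call(rbind, lapply(seq_len(n_nuisance_factors), function(j) {
      f <- rt(n, df = tail_df) * 3
      matrix(rep(f, each = features_per_factor), nrow = features_per_factor) +
        matrix(rnorm(features_per_factor * n, sd = 0.5),
               nrow = features_per_factor)
    }))
    sig_e <- matrix(rnorm(n_signal * n), nrow = n_signal)
    sig_e[, g2] <- sig_e[, g2] + rep_len(c(1, -1), n_signal) * effect_size
    expr <- rbind(sig_e, nuisance)
    rownames(expr) <- sprintf("gene_%05d", seq_len(nrow(expr)))
    colnames(expr) <- sample_ids

    # Methylation: logit-scale subtype block plus plain noise features.
    sig_m <- matrix(rnorm(n_signal * n), nrow = n_signal)
    sig_m[, g2] <- sig_m[, g2] + rep_len(c(-1, 1), n_signal) * effect_size
    noise_m <- matrix(rnorm(n_meth_noise * n), nrow = n_meth_noise)
    meth <- plogis(rbind(sig_m, noise_m) / 2)
    rownames(meth) <- sprintf("cpg_%05d", seq_len(nrow(meth)))
    colnames(meth) <- sample_ids

    lambda <- (1 / baseline_scale) * ifelse(g2, hazard_ratio, 1)
    t_event <- rexp(n, rate = lambda)
    if (censor_rate > 0) {
      t_cens <- rexp(n, rate = solve_censor_rate(lambda, censor_rate))
    } else {
      t_cens <- rep(Inf, n)
    }
    clinical <- tibble(sample_id = sample_ids,
                       time = pmin(t_event, t_cens),
                       event = as.integer(t_event <= t_cens),
                       age = rnorm(n, 50, 12),
                       gender = sample(c("female", "male"), n, replace = TRUE))
    structure(list(expr = expr, meth = meth, clinical = clinical,
                   true_labels = labels, true_driver_genes = character(0)),
              class = "synthetic_cohort")
  })
}
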
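#' Autoencoder hyperparameter configuration
#'
#' Five-layer symmetric autoencoder: input of width `input_dim`, three hidden
#' layers (default 500, 100 and 500 units) and an output layer back at
#' `input_dim`. Hidden layers use tanh; the output layer uses a sigmoid so
#' the cross-entropy (logloss) reconstruction objective is defined on
#' unit-interval inputs. Training adds an L1 penalty on every weight matrix
#' and an L2 penalty on every layer's activations, and uses plain minibatch
#' stochastic gradient descent with dropout on the hidden activations.
#'
#' The defaults are the reference settings of the subtyping workflow
#' (L1 `1e-4`, L2 activity `1e-3`, learning rate `1e-6`, 10 epochs, batch 32,
#' 50% dropout). The reference learning rate is conservative: at `1e-6` ten
#' epochs barely move the weights, so analyses that need a trained
#' representation typically raise it (the package's own validation runs use
#' `1e-3`); both are legitimate settings of the same model.
#'
#' @param input_dim Width `d` of the (concatenated) input.
#' @param hidden Hidden layer sizes, middle entry = bottleneck width.
#' @param l1_weight L1 penalty coefficient on the weight matrices.
#' @param l2_activity L2 penalty coefficient on layer activations
#'   (averaged over the batch).
#' @param learning_rate SGD step size.
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size.
#' @param dropout Dropout probability on hidden activations during training.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @param hidden_activation,output_activation Activation tags
#'   (`"tanh"`, `"sigmoid"` or `"linear"`).
#' @return A list of class `autoencoder_config` with a `layer_sizes` field
#'   `[d, hidden..., d]`.
#' @export
autoencoder_config <- function(input_dim,
                               hidden = c(500, 100, 500),
                               l1_weight = 1e-4,
                               l2_activity = 1e-3,
                               learning_rate = 1e-6,
                               epochs = 10,
                               batch_size = 32,
                               dropout = 0.5,
                               seed = 1,
                               hidden_activation = "tanh",
                               output_activation = "sigmoid") {
  check_scalar_num(input_dim, "input_dim", lower = 1, integer = TRUE)
  if (!is.numeric(hidden) || length(hidden) < 1L || any(hidden < 1)) {
    stop_config("hidden", "must be positive layer sizes")
  }
  bottleneck <- hidden[ceiling(length(hidden) / 2)]
  if (bottleneck >= input_dim) {
    stop_config("hidden", "bottleneck width must be smaller than input_dim")
  }
  check_scalar_num(l1_weight, "l1_weight", lower = 0)
  check_scalar_num(l2_activity, "l2_activity", lower = 0)
  check_scalar_num(learning_rate, "learning_rate", lower = 0)
  check_scalar_num(epochs, "epochs", lower = 1, integer = TRUE)
  check_scalar_num(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_scalar_num(dropout, "dropout", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar_num(seed, "seed", integer = TRUE)
  act_ok <- c("tanh", "sigmoid", "linear")
  if (!hidden_activation %in% act_ok) stop_config("hidden_activation", "unknown tag")
  if (!output_activation %in% act_ok) stop_config("output_activation", "unknown tag")
  structure(list(layer_sizes = c(as.integer(input_dim), as.integer(hidden),
                                 as.integer(input_dim)),
                 bottleneck_index = 1L + ceiling(length(hidden) / 2),
                 l1_weight = l1_weight,
                 l2_activity = l2_activity,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 dropout = dropout,
                 seed = as.integer(seed),
                 hidden_activation = hidden_activation,
                 output_activation = output_activation),
            class = "autoencoder_config")
}

apply_activation <- function(z, tag) {
  switch(tag,
         tanh = tanh(z),
         sigmoid = plogis(z),
         linear = z,
         abort(sprintf("unknown activation '%s'", tag)))
}

# Derivative of the activation expressed through its output a = act(z).
activation_grad <- function(a, tag) {
  switch(tag,
         tanh = 1 - a^2,
         sigmoid = a * (1 - a),
         linear = array(1, dim = dim(a) %||% length(a)),
         abort(sprintf("unknown activation '%s'", tag)))
}

#' Single-layer affine-plus-activation transform
#'
#' Computes `activation(W x + b)` for one layer. `W` follows the
#' `p x d` convention (output width by input width); `x` may be a single
#' `d`-vector or an `n x d` matrix of row-samples.
#'
#' @param x Input vector (length `d`) or matrix (`n x d`).
#' @param W Weight matrix, `p x d`.
#' @param b Intercept vector, length `p`.
#' @param activation `"tanh"`, `"sigmoid"` or `"linear"`.
#' @return The layer output, same row structure as `x`.
#' @export
layer_forward <- function(x, W, b, activation = "tanh") {
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(W)) {
    abort(sprintf("layer_forward: input width %d does not match W width %d",
                  ncol(x), ncol(W)), class = "aesurv_shape_error")
  }
  if (length(b) != nrow(W)) {
    abort("layer_forward: intercept length does not match W rows",
          class = "aesurv_shape_error")
  }
  z <- tcrossprod(x, W)
  z <- sweep(z, 2L, b, "+")
  a <- apply_activation(z, activation)
  if (vec_in) drop(a) else a
}

#' Cross-entropy reconstruction loss
#'
#' The summed binary cross-entropy between a target vector `x` in `[0,1]`
#' and a reconstruction `x_prime` in the open unit interval:
#' `-sum(x*log(x') + (1-x)*log(1-x'))`. Non-negative, minimized over
#' `x_prime` at `x_prime = x`, and symmetric under complementing both
#' arguments.
#'
#' @param x Target values in `[0, 1]` (vector or matrix).
#' @param x_prime Reconstructed values in `(0, 1)`, same shape.
#' @return A single non-negative number (summed over all entries; for a
#'   matrix this is the batch total, not the mean).
#' @export
reconstruction_logloss <- function(x, x_prime) {
  if (length(x) != length(x_prime)) {
    abort("reconstruction_logloss: shapes differ", class = "aesurv_shape_error")
  }
  if (any(x < 0 | x > 1)) abort("`x` must lie in [0, 1]")
  if (any(x_prime <= 0 | x_prime >= 1)) {
    abort("`x_prime` must lie strictly inside (0, 1)", class = "aesurv_domain_error")
  }
  -sum(x * log(x_prime) + (1 - x) * log(1 - x_prime))
}

new_autoencoder_model <- function(config, weights, biases) {
  k <- length(config$layer_sizes) - 1L
  activations <- c(rep(config$hidden_activation, k - 1L), config$output_activation)
  structure(list(weights = weights, biases = biases,
                 activations = activations, config = config,
                 fitted = FALSE, loss_trajectory = numeric(0)),
            class = "autoencoder_model")
}

# Seeded Glorot-uniform initialization; biases start at zero.
init_autoencoder <- function(config) {
  sizes <- config$layer_sizes
  k <- length(sizes) - 1L
  weights <- vector("list", k)
  biases <- vector("list", k)
  for (i in seq_len(k)) {
    d_in <- sizes[i]; d_out <- sizes[i + 1L]
    lim <- sqrt(6 / (d_in + d_out))
    weights[[i]] <- matrix(runif(d_out * d_in, -lim, lim), nrow = d_out)
    biases[[i]] <- numeric(d_out)
  }
  new_autoencoder_model(config, weights, biases)
}

# Forward pass through all layers. X is n x d (row-samples). Optional
# dropout masks (list, one per hidden layer, same shape as the activation)
# are applied multiplicatively after the activation (inverted dropout).
ae_forward <- function(model, X, masks = NULL) {
  k <- length(model$weights)
  A <- vector("list", k + 1L)
  A[[1L]] <- X
  for (i in seq_len(k)) {
    a <- layer_forward(A[[i]], model$weights[[i]], model$biases[[i]],
                       model$activations[i])
    if (!is.matrix(a)) a <- matrix(a, nrow = nrow(X))
    if (!is.null(masks) && i < k && !is.null(masks[[i]])) a <- a * masks[[i]]
    A[[i + 1L]] <- a
  }
  A
}

clamp_unit <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Loss pieces given precomputed activations A (from ae_forward).
ae_loss_from_forward <- function(model, A, X, config) {
  n <- nrow(X)
  recon <- reconstruction_logloss(X, clamp_unit(A[[length(A)]])) / n
  l1 <- config$l1_weight * sum(vapply(model$weights, function(W) sum(abs(W)), 0))
  act <- config$l2_activity *
    sum(vapply(A[-1L], function(a) sum(a^2), 0)) / n
  c(total = recon + l1 + act, recon = recon, l1 = l1, activity = act)
}

#' Total training objective of the autoencoder
#'
#' Mean cross-entropy reconstruction loss over the batch, plus the L1
#' penalty on every weight matrix and the L2 activity penalty on every
#' layer's activations (averaged over the batch). With both penalty
#' coefficients zero this equals the mean reconstruction loss exactly.
#'
#' @param model An `autoencoder_model` (fitted or freshly initialized).
#' @param batch `n x d` matrix of unit-interval inputs.
#' @param config Optional `autoencoder_config`; defaults to the model's own.
#' @return A single non-negative number.
#' @export
total_loss <- function(model, batch, config = model$config) {
  if (!is.matrix(batch)) batch <- matrix(batch, nrow = 1L)
  if (ncol(batch) != model$config$layer_sizes[1L]) {
    abort("total_loss: batch width does not match model input width",
          class = "aesurv_shape_error")
  }
  A <- ae_forward(model, batch)
  unname(ae_loss_from_forward(model, A, batch, config)[["total"]])
}

#' Gradients of the autoencoder objective
#'
#' Backpropagation of [total_loss()] with respect to every weight matrix and
#' intercept vector. Exposed so the analytic gradients can be checked
#' against finite differences.
#'
#' @inheritParams total_loss
#' @param masks Optional dropout masks (training internals).
#' @return A list with `weights` and `biases` gradient lists and the `loss`
#'   value at the evaluation point.
#' @export
loss_gradients <- function(model, batch, config = model$config, masks = NULL) {
  if (!is.matrix(batch)) batch <- matrix(batch, nrow = 1L)
  X <- batch
  n <- nrow(X)
  k <- length(model$weights)
  A <- ae_forward(model, X, masks)
  loss <- ae_loss_from_forward(model, A, X, config)[["total"]]

  gW <- vector("list", k)
  gb <- vector("list", k)
  out <- clamp_unit(A[[k + 1L]])
  # Output layer: cross-entropy + sigmoid collapses to (a - x)/n; for other
  # output activations chain through the activation derivative explicitly.
  if (model$activations[k] == "sigmoid") {
    dZ <- (out - X) / n
    dZ <- dZ + (2 * config$l2_activity / n) * A[[k + 1L]] *
      activation_grad(A[[k + 1L]], "sigmoid")
  } else {
    dA <- (-(X / out) + (1 - X) / (1 - out)) / n +
      (2 * config$l2_activity / n) * A[[k + 1L]]
    dZ <- dA * activation_grad(A[[k + 1L]], model$activations[k])
  }
  for (i in rev(seq_len(k))) {
    gW[[i]] <- crossprod(dZ, A[[i]]) + config$l1_weight * sign(model$weights[[i]])
    gb[[i]] <- colSums(dZ)
    if (i > 1L) {
      dA <- dZ %*% model$weights[[i]] +
        (2 * config$l2_activity / n) * A[[i]]
      if (!is.null(masks) && (i - 1L) < k && !is.null(masks[[i - 1L]])) {
        # A[[i]] is the post-dropout activation m * act(z); d act(z) needs the
        # raw activation, recovered by undoing the mask where it is non-zero.
        m <- masks[[i - 1L]]
        raw <- A[[i]]
        raw[m > 0] <- raw[m > 0] / m[m > 0]
        dZ <- dA * m * activation_grad(raw, model$activations[i - 1L])
      } else {
        dZ <- dA * activation_grad(A[[i]], model$activations[i - 1L])
      }
    }
  }
  list(weights = gW, biases = gb, loss = loss)
}

#' Train the autoencoder by minibatch stochastic gradient descent
#'
#' Shuffles samples each epoch, draws fresh dropout masks per minibatch, and
#' takes plain SGD steps on [total_loss()]. The per-epoch mean minibatch
#' loss is recorded as the training trajectory. Fully deterministic given
#' `config$seed`.
#'
#' @param data `n x d` matrix of unit-interval inputs, one row per sample
#'   (use [preprocess_omics()] / [squash_to_unit()] upstream). Rownames are
#'   kept as sample ids.
#' @param config An [autoencoder_config()]; its `input_dim` must equal
#'   `ncol(data)`.
#' @return A fitted `autoencoder_model` with a `loss_trajectory` field.
#' @export
train_autoencoder <- function(data, config) {
  if (!inherits(config, "autoencoder_config")) abort("`config` must be an autoencoder_config")
  if (!is.matrix(data)) abort("`data` must be a samples-by-features matrix")
  if (anyNA(data)) abort("`data` must not contain missing values")
  if (ncol(data) != config$layer_sizes[1L]) {
    abort(sprintf("config input_dim (%d) does not match data width (%d)",
                  config$layer_sizes[1L], ncol(data)), class = "aesurv_shape_error")
  }
  if (nrow(data) < config$batch_size) {
    abort("`data` must have at least `batch_size` samples")
  }
  withr::with_seed(config$seed, train_autoencoder_impl(data, config))
}

train_autoencoder_impl <- function(data, config) {
  model <- init_autoencoder(config)
  n <- nrow(data)
  k <- length(model$weights)
  lr <- config$learning_rate
  keep <- 1 - config$dropout
  trajectory <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    batch_losses <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- ord[starts[b]:min(starts[b] + config$batch_size - 1L, n)]
      X <- data[idx, , drop = FALSE]
      masks <- NULL
      if (config$dropout > 0) {
        masks <- lapply(seq_len(k - 1L), function(i) {
          p <- config$layer_sizes[i + 1L]
          matrix((runif(length(idx) * p) < keep) / keep, nrow = length(idx))
        })
      }
      g <- loss_gradients(model, X, config, masks)
      if (!is.finite(g$loss)) {
        abort(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
              class = "aesurv_divergence_error")
      }
      batch_losses[b] <- g$loss
      for (i in seq_len(k)) {
        model$weights[[i]] <- model$weights[[i]] - lr * g$weights[[i]]
        model$biases[[i]] <- model$biases[[i]] - lr * g$biases[[i]]
      }
    }
    trajectory[epoch] <- mean(batch_losses)
  }
  model$fitted <- TRUE
  model$loss_trajectory <- trajectory
  model
}

#' Extract bottleneck features
#'
#' Deterministic forward pass (dropout disabled) up to the bottleneck layer.
#' Row order follows the input; columns are named `AE_001`, `AE_002`, ...
#'
#' @param model A fitted `autoencoder_model`.
#' @param data `n x d` matrix of unit-interval inputs with sample rownames.
#' @return An `n x bottleneck` matrix of latent features.
#' @export
encode_samples <- function(model, data) {
  if (!inherits(model, "autoencoder_model")) abort("`model` must be an autoencoder_model")
  if (!model$fitted) abort("`model` has not been trained; call train_autoencoder() first")
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  if (ncol(data) != model$config$layer_sizes[1L]) {
    abort(sprintf("encode_samples: data width %d does not match model input width %d",
                  ncol(data), model$config$layer_sizes[1L]),
          class = "aesurv_shape_error")
  }
  bi <- model$config$bottleneck_index
  a <- data
  for (i in seq_len(bi - 1L)) {
    a <- layer_forward(a, model$weights[[i]], model$biases[[i]], model$activations[i])
    if (!is.matrix(a)) a <- matrix(a, nrow = nrow(data))
  }
  colnames(a) <- sprintf("AE_%03d", seq_len(ncol(a)))
  rownames(a) <- rownames(data)
  a
}

#' @export
print.autoencoder_model <- function(x, ...) {
  cat(sprintf("Autoencoder: layers [%s], activations [%s]\n",
              paste(x$config$layer_sizes, collapse = ", "),
              paste(x$activations, collapse = ", ")))
  if (x$fitted) {
    cat(sprintf("  trained %d epochs; loss %.4f -> %.4f\n",
                length(x$loss_trajectory),
                x$loss_trajectory[1L], x$loss_trajectory[length(x$loss_trajectory)]))
  } else {
    cat("  not trained\n")
  }
  invisible(x)
}

#' @describeIn train_autoencoder Tidy per-epoch training losses.
#' @param x,... Tidier arguments.
#' @method tidy autoencoder_model
#' @export
tidy.autoencoder_model <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_trajectory), loss = x$loss_trajectory)
}

#' @describeIn train_autoencoder One-row training summary.
#' @method glance autoencoder_model
#' @export
glance.autoencoder_model <- function(x, ...) {
  n_par <- sum(vapply(x$weights, length, 0L)) + sum(vapply(x$biases, length, 0L))
  tibble(n_layers = length(x$weights),
         bottleneck = x$config$layer_sizes[x$config$bottleneck_index],
         n_parameters = n_par,
         epochs = length(x$loss_trajectory),
         initial_loss = if (x$fitted) x$loss_trajectory[1L] else NA_real_,
         final_loss = if (x$fitted) x$loss_trajectory[length(x$loss_trajectory)] else NA_real_)
}

#' Save / load an autoencoder checkpoint
#'
#' The checkpoint is a single RDS archive holding weights, configuration and
#' the training-loss trajectory.
#'
#' @param model A fitted `autoencoder_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, "autoencoder_model")) abort("`model` must be an autoencoder_model")
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "autoencoder_model")) abort("checkpoint does not contain an autoencoder_model")
  model
}
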
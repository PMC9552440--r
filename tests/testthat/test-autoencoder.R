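test_that("layer_forward computes activation(Wx + b) with shape checks", {
  W <- matrix(0, 3, 2); b <- rep(0, 3)
  expect_equal(layer_forward(c(1, 2), W, b, "tanh"), rep(0, 3))

  W2 <- diag(2); eps <- 1e-6
  expect_equal(layer_forward(c(eps, -eps), W2, c(0, 0), "tanh"),
               c(eps, -eps), tolerance = 1e-10)

  expect_error(layer_forward(c(1, 2), matrix(1, 2, 3), rep(0, 2)),
               class = "aesurv_shape_error")

  s <- layer_forward(c(10, -10), diag(2), c(0, 0), "sigmoid")
  expect_true(all(s > 0 & s < 1))
})

test_that("reconstruction_logloss matches closed forms and is symmetric", {
  expect_equal(reconstruction_logloss(1, 0.5), log(2), tolerance = 1e-10)
  expect_equal(reconstruction_logloss(c(1, 0), c(0.9, 0.1)), -2 * log(0.9),
               tolerance = 1e-10)
  expect_equal(reconstruction_logloss(0.5, 0.5), log(2), tolerance = 1e-10)
  # minimum over x' at x' = x
  expect_gt(reconstruction_logloss(0.5, 0.4), reconstruction_logloss(0.5, 0.5))

  x <- runif(10); xp <- runif(10, 0.05, 0.95)
  expect_equal(reconstruction_logloss(x, xp),
               reconstruction_logloss(1 - x, 1 - xp), tolerance = 1e-12)

  expect_error(reconstruction_logloss(1, 1), class = "aesurv_domain_error")
})

test_that("total_loss equals the explicit-loop oracle on a hand-sized net", {
  model <- tiny_ae_model(seed = 3)
  batch <- matrix(c(0.2, 0.8, 0.6, 0.4, 0.5, 0.1), ncol = 2, byrow = TRUE)
  expect_equal(total_loss(model, batch),
               oracle_total_loss(model, batch, model$config), tolerance = 1e-12)

  # penalties off -> exactly the mean reconstruction loss
  cfg0 <- model$config; cfg0$l1_weight <- 0; cfg0$l2_activity <- 0
  A <- aesurv:::ae_forward(model, batch)
  recon <- reconstruction_logloss(batch, A[[length(A)]]) / nrow(batch)
  expect_equal(total_loss(model, batch, cfg0), recon, tolerance = 1e-12)

  # zero weights contribute nothing through the L1 term
  zero <- model
  zero$weights <- lapply(zero$weights, function(W) W * 0)
  cfg_l1 <- cfg0; cfg_l1$l1_weight <- 10
  expect_equal(total_loss(zero, batch, cfg_l1), total_loss(zero, batch, cfg0),
               tolerance = 1e-12)
})

test_that("backprop gradients match central finite differences", {
  model <- tiny_ae_model(seed = 5)
  batch <- matrix(runif(8, 0.1, 0.9), ncol = 2)
  analytic <- loss_gradients(model, batch)
  numeric <- oracle_gradients_fd(model, batch, model$config)
  expect_lt(max_relative_gradient_error(analytic, numeric), 1e-4)
})

test_that("training is seed-deterministic and a zero learning rate is a no-op", {
  data <- matrix(runif(60 * 8, 0.1, 0.9), nrow = 60,
                 dimnames = list(sprintf("S%02d", 1:60), NULL))
  cfg <- autoencoder_config(input_dim = 8, hidden = c(6, 3, 6),
                            learning_rate = 0.01, epochs = 5, batch_size = 10,
                            dropout = 0.5, seed = 42)
  m1 <- train_autoencoder(data, cfg)
  m2 <- train_autoencoder(data, cfg)
  expect_identical(m1$loss_trajectory, m2$loss_trajectory)
  expect_identical(m1$weights, m2$weights)

  cfg0 <- autoencoder_config(input_dim = 8, hidden = c(6, 3, 6),
                             learning_rate = 0, epochs = 3, batch_size = 10,
                             dropout = 0, seed = 42)
  frozen <- train_autoencoder(data, cfg0)
  init <- withr::with_seed(42, aesurv:::init_autoencoder(cfg0))
  expect_identical(frozen$weights, init$weights)
  expect_lt(diff(range(frozen$loss_trajectory)), 1e-10)
})

test_that("a workable learning rate reduces the training loss", {
  withr::with_seed(1, {
    base <- matrix(runif(80 * 3), nrow = 80)
    data <- cbind(base, base, base, base)[, 1:10]
    data <- pmin(pmax(data + rnorm(800, sd = 0.02), 0.01), 0.99)
    rownames(data) <- sprintf("S%02d", 1:80)
  })
  cfg <- autoencoder_config(input_dim = 10, hidden = c(8, 3, 8),
                            learning_rate = 5e-2, epochs = 100, batch_size = 16,
                            dropout = 0, seed = 2)
  fit <- train_autoencoder(data, cfg)
  expect_lt(fit$loss_trajectory[100], 0.9 * fit$loss_trajectory[1])
  # smoothed trajectory is non-increasing overall
  sm <- stats::filter(fit$loss_trajectory, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
})

test_that("encoding is deterministic, shape-faithful and order-equivariant", {
  data <- matrix(runif(40 * 6, 0.1, 0.9), nrow = 40,
                 dimnames = list(sprintf("S%02d", 1:40), NULL))
  cfg <- autoencoder_config(input_dim = 6, hidden = c(5, 2, 5),
                            learning_rate = 1e-3, epochs = 3, batch_size = 8,
                            seed = 7)
  model <- train_autoencoder(data, cfg)
  L1 <- encode_samples(model, data)
  L2 <- encode_samples(model, data)
  expect_identical(L1, L2)
  expect_identical(dim(L1), c(40L, 2L))
  expect_identical(colnames(L1), c("AE_001", "AE_002"))

  perm <- sample(40)
  Lp <- encode_samples(model, data[perm, ])
  expect_equal(Lp, L1[perm, ], tolerance = 1e-12)

  single <- encode_samples(model, data[1, , drop = FALSE])
  expect_identical(nrow(single), 1L)

  expect_error(encode_samples(model, data[, 1:5]), class = "aesurv_shape_error")
})

test_that("checkpoints round-trip through a single archive", {
  data <- matrix(runif(32 * 4, 0.1, 0.9), nrow = 32,
                 dimnames = list(sprintf("S%02d", 1:32), NULL))
  cfg <- autoencoder_config(input_dim = 4, hidden = c(3, 2, 3),
                            learning_rate = 1e-3, epochs = 2, batch_size = 8,
                            seed = 1)
  model <- train_autoencoder(data, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$weights, model$weights)
  expect_identical(encode_samples(back, data), encode_samples(model, data))
})
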
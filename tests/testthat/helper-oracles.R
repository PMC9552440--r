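# Independent oracle implementations used to validate the package's fast
# paths. Deliberately naive: explicit loops and direct formula evaluation.

# Harrell's C by brute-force enumeration of every ordered pair.
oracle_concordance <- function(time, event, risk) {
  conc <- 0; tied <- 0; perm <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      permissible <- (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (!permissible) next
      perm <- perm + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) tied <- tied + 1
    }
  }
  if (perm == 0) return(NA_real_)
  (conc + 0.5 * tied) / perm
}

# Log-rank chi-square by a manual risk-table tally over pooled event times.
oracle_logrank <- function(time, event, group) {
  group <- as.character(group)
  lev <- sort(unique(group))
  stopifnot(length(lev) == 2L)
  evt_times <- sort(unique(time[event == 1]))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in evt_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & group == lev[1L])
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lev[1L])
    o1 <- o1 + d1
    e1 <- e1 + d_t * n1 / n_t
    if (n_t > 1) {
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  (o1 - e1)^2 / v
}

# Exact hypergeometric upper tail by direct summation of the pmf.
oracle_hypergeom_tail <- function(overlap, set_size, universe_size, query_size) {
  hi <- min(set_size, query_size)
  if (overlap > hi) return(0)
  sum(vapply(overlap:hi, function(x) {
    choose(set_size, x) * choose(universe_size - set_size, query_size - x) /
      choose(universe_size, query_size)
  }, 0))
}

# Autoencoder objective evaluated with explicit loops (no matrix algebra).
oracle_total_loss <- function(model, batch, config) {
  n <- nrow(batch)
  act <- function(z, tag) switch(tag, tanh = tanh(z), sigmoid = 1 / (1 + exp(-z)),
                                 linear = z)
  total_recon <- 0
  total_act <- 0
  for (s in seq_len(n)) {
    a <- batch[s, ]
    for (i in seq_along(model$weights)) {
      W <- model$weights[[i]]; b <- model$biases[[i]]
      z <- numeric(nrow(W))
      for (p in seq_len(nrow(W))) {
        acc <- b[p]
        for (d in seq_len(ncol(W))) acc <- acc + W[p, d] * a[d]
        z[p] <- acc
      }
      a <- act(z, model$activations[i])
      total_act <- total_act + sum(a^2)
    }
    x <- batch[s, ]
    total_recon <- total_recon - sum(x * log(a) + (1 - x) * log(1 - a))
  }
  l1 <- 0
  for (W in model$weights) l1 <- l1 + sum(abs(W))
  total_recon / n + config$l1_weight * l1 + config$l2_activity * total_act / n
}

# Central finite differences of total_loss over every parameter.
oracle_gradients_fd <- function(model, batch, config, eps = 1e-5) {
  gW <- vector("list", length(model$weights))
  gb <- vector("list", length(model$biases))
  for (i in seq_along(model$weights)) {
    W <- model$weights[[i]]
    g <- W * 0
    for (idx in seq_along(W)) {
      mp <- model; mp$weights[[i]][idx] <- W[idx] + eps
      mm <- model; mm$weights[[i]][idx] <- W[idx] - eps
      g[idx] <- (total_loss(mp, batch, config) - total_loss(mm, batch, config)) / (2 * eps)
    }
    gW[[i]] <- g
    b <- model$biases[[i]]
    gb[[i]] <- vapply(seq_along(b), function(idx) {
      mp <- model; mp$biases[[i]][idx] <- b[idx] + eps
      mm <- model; mm$biases[[i]][idx] <- b[idx] - eps
      (total_loss(mp, batch, config) - total_loss(mm, batch, config)) / (2 * eps)
    }, 0)
  }
  list(weights = gW, biases = gb)
}

max_relative_gradient_error <- function(analytic, numeric) {
  errs <- c()
  for (i in seq_along(analytic$weights)) {
    a <- c(analytic$weights[[i]], analytic$biases[[i]])
    f <- c(numeric$weights[[i]], numeric$biases[[i]])
    errs <- c(errs, abs(a - f) / pmax(abs(a) + abs(f), 1e-8))
  }
  max(errs)
}
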
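#' Univariate Cox proportional-hazards screening of latent features
#'
#' Fits one single-covariate Cox model per latent feature
#' (`survival::coxph`, Breslow ties) and keeps features whose Wald-test
#' p-value falls below `alpha`. Features for which the fit fails to converge
#' are flagged unselected with a diagnostic note instead of aborting.
#'
#' @param latent Samples-by-features matrix of latent features (rownames are
#'   sample ids), e.g. from [encode_samples()] or [pca_transform()].
#' @param clinical Clinical tibble with `sample_id`, `time`, `event`.
#' @param alpha Selection threshold on the Wald p-value (default 0.05).
#' @return A tibble with one row per feature: `feature`, `coefficient`,
#'   `p_value`, `selected`, `note`.
#' @export
cox_screen <- function(latent, clinical, alpha = 0.05) {
  if (!is.matrix(latent)) abort("`latent` must be a samples-by-features matrix")
  check_clinical(clinical)
  check_scalar_num(alpha, "alpha", lower = 0, upper = 1)
  if (is.null(rownames(latent))) abort("`latent` must carry sample rownames")
  check_aligned(rownames(latent), clinical)
  cl <- clinical[match(rownames(latent), clinical$sample_id), ]
  surv <- survival::Surv(cl$time, cl$event)
  feats <- colnames(latent) %||% sprintf("F%03d", seq_len(ncol(latent)))

  rows <- purrr::map(seq_len(ncol(latent)), function(j) {
    x <- latent[, j]
    if (sd(x) == 0) {
      return(tibble(feature = feats[j], coefficient = NA_real_,
                    p_value = NA_real_, selected = FALSE,
                    note = "constant feature"))
    }
    fit <- tryCatch(
      suppressWarnings(survival::coxph(surv ~ x, ties = "breslow",
                                       control = survival::coxph.control(iter.max = 50,
                                                                         eps = 1e-7))),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit)[1L])) {
      return(tibble(feature = feats[j], coefficient = NA_real_,
                    p_value = NA_real_, selected = FALSE,
                    note = "did not converge"))
    }
    z <- coef(fit)[1L] / sqrt(fit$var[1L, 1L])
    p <- 2 * stats::pnorm(-abs(z))
    tibble(feature = feats[j], coefficient = unname(coef(fit)[1L]),
           p_value = p, selected = is.finite(p) && p < alpha,
           note = NA_character_)
  })
  out <- bind_rows(rows)
  attr(out, "alpha") <- alpha
  out
}

calinski_harabasz <- function(fit, n) {
  k <- length(fit$size)
  if (fit$tot.withinss <= 0) return(Inf)  # perfectly tight clusters
  (fit$betweenss / (k - 1)) / (fit$tot.withinss / (n - k))
}

#' K-means clustering with data-driven choice of the cluster number
#'
#' Runs K-means (`stats::kmeans`, 10 restarts, seeded) for every candidate
#' `k`, scores each solution with the Calinski-Harabasz index and the mean
#' silhouette width, and picks the `k` maximizing Calinski-Harabasz
#' (ties: larger silhouette, then smaller `k`).
#'
#' @param latent_selected Samples-by-features matrix restricted to the
#'   survival-associated features.
#' @param k_min,k_max Candidate cluster-number range (default 2..6).
#' @param seed Integer seed; the same seed reproduces identical labels.
#' @param nstart Random restarts per candidate `k`.
#' @return A list of class `cluster_selection`: `scores` (tibble of `k`,
#'   `calinski_harabasz`, `silhouette`), `chosen_k`, `labels` (named integer
#'   vector in `1..chosen_k`) and `fits`-free diagnostics.
#' @export
kmeans_select <- function(latent_selected, k_min = 2, k_max = 6, seed = 1,
                          nstart = 10) {
  if (!is.matrix(latent_selected) || ncol(latent_selected) < 1L) {
    abort("no features supplied for clustering; relax the screening alpha",
          class = "aesurv_selection_error")
  }
  check_scalar_num(k_min, "k_min", lower = 2, integer = TRUE)
  check_scalar_num(k_max, "k_max", lower = k_min, integer = TRUE)
  n <- nrow(latent_selected)
  if (n <= k_max) abort("need more samples than k_max to cluster")
  if (is.null(rownames(latent_selected))) {
    abort("`latent_selected` must carry sample rownames")
  }
  d <- stats::dist(latent_selected)
  ks <- k_min:k_max
  results <- withr::with_seed(seed, purrr::map(ks, function(k) {
    fit <- kmeans(latent_selected, centers = k, nstart = nstart,
                  iter.max = 100)
    sil <- mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
    list(fit = fit, ch = calinski_harabasz(fit, n), sil = sil)
  }))
  scores <- tibble(k = ks,
                   calinski_harabasz = map_dbl(results, "ch"),
                   silhouette = map_dbl(results, "sil"))
  ord <- order(-scores$calinski_harabasz, -scores$silhouette, scores$k)
  chosen <- ord[1L]
  labels <- results[[chosen]]$fit$cluster
  names(labels) <- rownames(latent_selected)
  structure(list(scores = scores,
                 chosen_k = ks[chosen],
                 labels = labels,
                 centers = results[[chosen]]$fit$centers),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("Cluster selection over k = %d..%d; chosen k = %d\n",
              min(x$scores$k), max(x$scores$k), x$chosen_k))
  print(x$scores)
  invisible(x)
}

#' @describeIn kmeans_select Tidy the per-k selection scores.
#' @param x,... Tidier arguments.
#' @method tidy cluster_selection
#' @export
tidy.cluster_selection <- function(x, ...) {
  mutate(x$scores, chosen = .data$k == x$chosen_k)
}

#' Name clusters by prognosis
#'
#' Renames clusters `G1..Gk` in decreasing order of median observed survival
#' time, so `G1` is the best-prognosis and the last group the
#' worst-prognosis subtype. Ties are broken by larger mean survival, then by
#' cluster size (descending). A pure relabeling: the partition is unchanged.
#'
#' @param selection A `cluster_selection` from [kmeans_select()], or a named
#'   vector of cluster labels.
#' @param clinical Clinical tibble covering the clustered samples.
#' @return A tibble of class `subtype_result` with `sample_id` and `subtype`
#'   (factor `G1..Gk`); the selection diagnostics are kept in the
#'   `"selection"` attribute.
#' @export
name_subtypes <- function(selection, clinical) {
  labels <- if (inherits(selection, "cluster_selection")) selection$labels else selection
  if (is.null(names(labels))) abort("cluster labels must be named by sample id")
  check_clinical(clinical)
  check_aligned(names(labels), clinical)
  cl <- clinical[match(names(labels), clinical$sample_id), ]
  groups <- split(seq_along(labels), labels)
  if (any(lengths(groups) == 0L)) abort("empty cluster encountered")
  stats_by_cluster <- tibble(
    cluster = names(groups),
    median_time = map_dbl(groups, ~ median(cl$time[.x])),
    mean_time = map_dbl(groups, ~ mean(cl$time[.x])),
    size = lengths(groups)
  )
  if (any(map_dbl(groups, ~ sum(cl$event[.x])) == 0 &
          map_dbl(groups, ~ sum(cl$time[.x])) == 0)) {
    abort("a cluster has no events and no observed time; cannot order by prognosis")
  }
  ord <- order(-stats_by_cluster$median_time, -stats_by_cluster$mean_time,
               -stats_by_cluster$size)
  new_names <- setNames(sprintf("G%d", seq_along(ord)),
                        stats_by_cluster$cluster[ord])
  subtype <- factor(unname(new_names[as.character(labels)]),
                    levels = sprintf("G%d", seq_along(ord)))
  out <- tibble(sample_id = names(labels), subtype = subtype)
  class(out) <- c("subtype_result", class(out))
  attr(out, "selection") <- if (inherits(selection, "cluster_selection")) selection else NULL
  attr(out, "ordering") <- "decreasing median survival (ties: mean, then size)"
  out
}

#' @describeIn name_subtypes Per-subtype summary: size, events, median time.
#' @param x,... Tidier arguments.
#' @param clinical Clinical tibble (required for survival columns).
#' @method glance subtype_result
#' @export
glance.subtype_result <- function(x, clinical = NULL, ...) {
  counts <- as.data.frame(table(x$subtype))
  out <- tibble(subtype = as.character(counts$Var1), n = counts$Freq)
  if (!is.null(clinical)) {
    cl <- left_join(as_tibble(x), clinical, by = "sample_id")
    surv_stats <- cl |>
      group_by(.data$subtype) |>
      summarise(events = sum(.data$event),
                median_time = median(.data$time), .groups = "drop") |>
      mutate(subtype = as.character(.data$subtype))
    out <- left_join(out, surv_stats, by = "subtype")
  }
  out
}

#' Subtype discovery from latent features
#'
#' Convenience wrapper chaining [cox_screen()], [kmeans_select()] and
#' [name_subtypes()]: the screen-then-cluster recipe applied to any latent
#' representation.
#'
#' @inheritParams cox_screen
#' @inheritParams kmeans_select
#' @return A list with `subtypes` (a `subtype_result`), `screen` (the
#'   Cox-screen tibble) and `selection` (the `cluster_selection`).
#' @export
discover_subtypes <- function(latent, clinical, alpha = 0.05, k_min = 2,
                              k_max = 6, seed = 1) {
  screen <- cox_screen(latent, clinical, alpha = alpha)
  keep <- screen$feature[screen$selected]
  if (!length(keep)) {
    abort("no latent features pass the survival screen; relax `alpha`",
          class = "aesurv_selection_error")
  }
  selection <- kmeans_select(latent[, keep, drop = FALSE], k_min = k_min,
                             k_max = k_max, seed = seed)
  subtypes <- name_subtypes(selection, clinical)
  list(subtypes = subtypes, screen = screen, selection = selection)
}
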
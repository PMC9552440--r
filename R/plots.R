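#' Plot the autoencoder training trajectory
#'
#' @param object A fitted `autoencoder_model`.
#' @param ... Unused.
#' @return A ggplot of per-epoch mean minibatch loss.
#' @method autoplot autoencoder_model
#' @export
autoplot.autoencoder_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Epoch", y = "Training loss",
                  title = "Autoencoder training trajectory") +
    ggplot2::theme_minimal()
}

#' Plot cluster-number selection diagnostics
#'
#' Calinski-Harabasz and mean silhouette width per candidate `k`, with the
#' chosen `k` highlighted.
#'
#' @param object A `cluster_selection` from [kmeans_select()].
#' @param ... Unused.
#' @return A faceted ggplot.
#' @method autoplot cluster_selection
#' @export
autoplot.cluster_selection <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("calinski_harabasz", "silhouette"),
                        names_to = "score", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d95f02", `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::facet_wrap(~score, scales = "free_y") +
    ggplot2::labs(x = "Number of clusters k", y = NULL,
                  title = "Cluster-number selection") +
    ggplot2::theme_minimal()
}

# Kaplan-Meier step curves per group, computed with survival::survfit.
km_steps <- function(clinical, groups) {
  fit <- survival::survfit(survival::Surv(clinical$time, clinical$event) ~ groups)
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  tibble(time = fit$time, surv = fit$surv,
         group = sub("^groups=", "", strata)) |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(tibble(time = 0, surv = 1), .x)) |>
    ungroup()
}

#' Kaplan-Meier curves by subtype
#'
#' @param object A `subtype_result`.
#' @param clinical Clinical tibble covering the labeled samples.
#' @param ... Unused.
#' @return A ggplot of per-subtype Kaplan-Meier survival curves, annotated
#'   with the log-rank p-value.
#' @method autoplot subtype_result
#' @export
autoplot.subtype_result <- function(object, clinical, ...) {
  df <- left_join(as_tibble(object), clinical, by = "sample_id")
  steps <- km_steps(df, df$subtype)
  lr <- logrank_test(object, clinical)
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$surv,
                                      colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = "Subtype",
                  title = "Survival by subtype",
                  subtitle = sprintf("log-rank p = %.3g", lr$p_value)) +
    ggplot2::theme_minimal()
}

#' Methylation-expression driver-gene overview
#'
#' Spearman correlation against the between-subtype methylation difference,
#' colored by driver direction; the correlation threshold is drawn as a
#' dashed line.
#'
#' @param object A `driver_result` from [find_driver_genes()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot driver_result
#' @export
autoplot.driver_result <- function(object, ...) {
  thr <- attr(object, "thresholds")
  df <- mutate(as_tibble(object),
               meth_diff = .data$mean_meth_G2 - .data$mean_meth_G1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$meth_diff, y = .data$spearman_r,
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = thr[["r"]], linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(hypo_up = "#d95f02",
                                            hyper_down = "#1b9e77",
                                            none = "grey70")) +
    ggplot2::labs(x = "Methylation difference (G2 - G1)",
                  y = "Spearman r (methylation vs expression)",
                  colour = "Direction",
                  title = "Methylation-driven genes") +
    ggplot2::theme_minimal()
}
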
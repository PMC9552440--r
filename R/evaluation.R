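#' Harrell's concordance index
#'
#' Fraction of permissible patient pairs whose risk ordering agrees with
#' their survival ordering. A pair is permissible when the shorter observed
#' time belongs to a subject with an event (including event-vs-censored ties
#' in time, where the event subject is taken as the earlier failure); tied
#' event times are not comparable. Ties in the risk score count 0.5.
#'
#' @param predictions Tibble with `sample_id` and `risk_score` (higher =
#'   worse prognosis).
#' @param clinical Clinical tibble with `sample_id`, `time`, `event`.
#' @return A single value in `[0, 1]`; 0.5 is random, 1 perfect.
#' @export
concordance_index <- function(predictions, clinical) {
  if (!all(c("sample_id", "risk_score") %in% names(predictions))) {
    abort("`predictions` needs columns sample_id and risk_score")
  }
  check_clinical(clinical)
  df <- left_join(as_tibble(predictions), clinical, by = "sample_id")
  if (anyNA(df$time)) abort("some predicted samples are missing from `clinical`")
  time <- df$time; event <- df$event; risk <- df$risk_score
  n <- length(time)
  # Pairwise comparability: i earlier-with-event than j.
  t_i <- matrix(time, n, n); t_j <- t(t_i)
  e_i <- matrix(event == 1, n, n)
  e_j <- t(e_i)
  earlier <- (t_i < t_j & e_i) | (t_i == t_j & e_i & !e_j)
  r_i <- matrix(risk, n, n); r_j <- t(r_i)
  concordant <- sum(earlier & (r_i > r_j))
  tied <- sum(earlier & (r_i == r_j))
  permissible <- sum(earlier)
  if (permissible == 0) {
    abort("no permissible pairs; concordance is undefined",
          class = "aesurv_undefined_error")
  }
  (concordant + 0.5 * tied) / permissible
}

#' Binary Brier score of survival predictions
#'
#' Mean squared difference between the predicted event probability and the
#' observed event indicator. With `horizon` set, the outcome is instead
#' "event by `horizon`": subjects censored before the horizon are dropped as
#' ambiguous, subjects followed past it count as survivors.
#'
#' @param predictions Tibble with `sample_id` and `event_probability`.
#' @param clinical Clinical tibble.
#' @param horizon Optional time horizon (days).
#' @return A value in `[0, 1]`; lower is better.
#' @export
brier_score <- function(predictions, clinical, horizon = NULL) {
  if (!all(c("sample_id", "event_probability") %in% names(predictions))) {
    abort("`predictions` needs columns sample_id and event_probability")
  }
  check_clinical(clinical)
  p <- predictions$event_probability
  if (any(p < 0 | p > 1)) abort("event_probability must lie in [0, 1]")
  df <- left_join(as_tibble(predictions), clinical, by = "sample_id")
  if (is.null(horizon)) {
    y <- df$event
    keep <- rep(TRUE, nrow(df))
  } else {
    check_scalar_num(horizon, "horizon", lower = 0, strict_lower = TRUE)
    y <- as.integer(df$time <= horizon & df$event == 1)
    keep <- !(df$time < horizon & df$event == 0)  # censored before horizon
  }
  if (!any(keep)) abort("no subjects with a determinate outcome at this horizon")
  mean((df$event_probability[keep] - y[keep])^2)
}

#' Log-rank test between subtypes
#'
#' Standard k-group log-rank test of survival-curve equality
#' (`survival::survdiff`), reported as the chi-square statistic with `k - 1`
#' degrees of freedom and its p-value.
#'
#' @param labels A `subtype_result` (or tibble with `sample_id` and
#'   `subtype`).
#' @param clinical Clinical tibble.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(labels, clinical) {
  if (!all(c("sample_id", "subtype") %in% names(labels))) {
    abort("`labels` needs columns sample_id and subtype")
  }
  check_clinical(clinical)
  df <- left_join(as_tibble(labels), clinical, by = "sample_id")
  groups <- droplevels(factor(df$subtype))
  if (nlevels(groups) < 2L) abort("need at least two non-empty groups")
  fit <- survival::survdiff(survival::Surv(df$time, df$event) ~ groups)
  k <- nlevels(groups)
  tibble(statistic = unname(fit$chisq), df = k - 1L,
         p_value = pchisq(unname(fit$chisq), df = k - 1L, lower.tail = FALSE))
}

#' Aggregate per-fold evaluation metrics
#'
#' Mean and sample SD for the C-index and Brier score; the geometric mean
#' (exponentiated mean log, zeros floored at 1e-300) for log-rank p-values.
#'
#' @param per_fold Tibble with columns `c_index`, `brier`, `logrank_p` (one
#'   row per fold), e.g. a `cv_report`.
#' @return A one-row tibble of aggregates.
#' @export
aggregate_folds <- function(per_fold) {
  if (!nrow(per_fold)) abort("`per_fold` must contain at least one fold")
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  tibble(n_folds = nrow(per_fold),
         c_index_mean = mean(per_fold$c_index, na.rm = TRUE),
         c_index_sd = sd0(per_fold$c_index[!is.na(per_fold$c_index)]),
         brier_mean = mean(per_fold$brier, na.rm = TRUE),
         brier_sd = sd0(per_fold$brier[!is.na(per_fold$brier)]),
         logrank_p_geomean = geometric_mean_p(per_fold$logrank_p))
}

#' Between-subtype clinical covariate tests
#'
#' One test per covariate: Wilcoxon rank-sum (Kruskal-Wallis for more than
#' two subtypes) for continuous covariates, chi-square without continuity
#' correction on the subtype-by-category contingency table for categorical
#' ones. Covariates that are entirely missing are skipped with a warning.
#'
#' @param labels A `subtype_result`.
#' @param clinical Clinical tibble.
#' @param covariates Covariate column names; default every column except
#'   `sample_id`, `time`, `event`.
#' @return A tibble: `covariate`, `test`, `statistic`, `p_value`.
#' @export
covariate_tests <- function(labels, clinical, covariates = NULL) {
  if (!all(c("sample_id", "subtype") %in% names(labels))) {
    abort("`labels` needs columns sample_id and subtype")
  }
  check_clinical(clinical)
  df <- left_join(as_tibble(labels), clinical, by = "sample_id")
  groups <- droplevels(factor(df$subtype))
  if (nlevels(groups) < 2L) abort("need at least two non-empty subtypes")
  covariates <- covariates %||%
    setdiff(names(clinical), c("sample_id", "time", "event"))
  rows <- purrr::map(covariates, function(v) {
    x <- df[[v]]
    if (is.null(x) || all(is.na(x))) {
      warn(sprintf("covariate '%s' is missing entirely; skipped", v))
      return(NULL)
    }
    if (is.numeric(x)) {
      if (nlevels(groups) == 2L) {
        ht <- suppressWarnings(wilcox.test(x ~ groups, exact = FALSE))
        tibble(covariate = v, test = "wilcoxon",
               statistic = unname(ht$statistic), p_value = ht$p.value)
      } else {
        ht <- kruskal.test(x, groups)
        tibble(covariate = v, test = "kruskal",
               statistic = unname(ht$statistic), p_value = ht$p.value)
      }
    } else {
      tab <- table(groups, x)
      if (ncol(tab) < 2L) {
        return(tibble(covariate = v, test = "chi_square",
                      statistic = 0, p_value = 1))
      }
      ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
      tibble(covariate = v, test = "chi_square",
             statistic = unname(ht$statistic), p_value = ht$p.value)
    }
  })
  bind_rows(rows)
}

#' Compare Cox models over covariate sets
#'
#' Fits one multivariate proportional-hazards model per covariate set
#' (listwise deletion of missing values) and reports the in-sample C-index
#' of each, the device used to ask whether subtype labels add predictive
#' value over clinical covariates alone.
#'
#' @param clinical Clinical tibble.
#' @param labels A `subtype_result`; referenced in covariate sets as
#'   `"subtype"`.
#' @param covariate_sets Named list of character vectors of covariate names.
#' @return A tibble: `model`, `covariates`, `n`, `c_index`, `converged`.
#' @export
cox_compare <- function(clinical, labels,
                        covariate_sets = list(
                          full = c("age", "gender", "grade", "tumor_type", "subtype"),
                          subtype_only = "subtype",
                          tumor_type_only = "tumor_type")) {
  check_clinical(clinical)
  df <- left_join(as_tibble(labels), clinical, by = "sample_id")
  rows <- purrr::imap(covariate_sets, function(vars, name) {
    missing_vars <- setdiff(vars, names(df))
    if (length(missing_vars)) {
      abort(sprintf("covariate set '%s' references unknown column(s): %s",
                    name, paste(missing_vars, collapse = ", ")))
    }
    sub <- df[stats::complete.cases(df[c("time", "event", vars)]),
              c("time", "event", vars)]
    fit <- tryCatch(
      suppressWarnings(survival::coxph(
        survival::Surv(time, event) ~ .,
        data = as.data.frame(sub), ties = "breslow")),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(model = name, covariates = paste(vars, collapse = "+"),
                    n = nrow(sub), c_index = NA_real_, converged = FALSE))
    }
    conc <- unname(summary(fit)$concordance[1L])
    tibble(model = name, covariates = paste(vars, collapse = "+"),
           n = nrow(sub), c_index = conc,
           converged = is.finite(conc))
  })
  bind_rows(rows)
}
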
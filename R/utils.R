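# Internal validation helpers shared across modules.

stop_config <- function(field, msg) {
  abort(sprintf("Invalid configuration field `%s`: %s", field, msg),
        class = "aesurv_config_error")
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE,
                             integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(field, "must be a single finite number")
  }
  if (integer && x != round(x)) stop_config(field, "must be an integer")
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_config(field, sprintf("must lie in %s%s, %s%s",
                               if (strict_lower) "(" else "[", lower, upper,
                               if (strict_upper) ")" else "]"))
  }
  invisible(x)
}

check_omics_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric feature-by-sample matrix", arg))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("`%s` must carry feature rownames and sample colnames", arg))
  }
  if (anyDuplicated(rownames(m))) {
    abort(sprintf("`%s` has duplicated feature ids (e.g. %s)", arg,
                  rownames(m)[duplicated(rownames(m))][1L]))
  }
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("`%s` has duplicated sample ids (e.g. %s)", arg,
                  colnames(m)[duplicated(colnames(m))][1L]))
  }
  invisible(m)
}

check_clinical <- function(clinical, arg = "clinical") {
  req <- c("sample_id", "time", "event")
  miss <- setdiff(req, names(clinical))
  if (length(miss)) {
    abort(sprintf("`%s` is missing required columns: %s", arg,
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(clinical$sample_id)) abort("clinical sample_id must be unique")
  if (any(!is.finite(clinical$time)) || any(clinical$time <= 0)) {
    abort("clinical `time` must be strictly positive and finite")
  }
  if (!all(clinical$event %in% c(0, 1))) abort("clinical `event` must be 0/1")
  invisible(clinical)
}

# Match a vector of sample ids between a matrix (columns) and clinical rows,
# erroring when they disagree.
check_aligned <- function(sample_ids, clinical) {
  if (!identical(sort(sample_ids), sort(clinical$sample_id))) {
    abort("sample ids of the feature matrix and the clinical table differ; align_samples() first")
  }
  invisible(TRUE)
}

geometric_mean_p <- function(p, floor = 1e-300) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  exp(mean(log(pmax(p, floor))))
}
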
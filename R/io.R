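#' Read a feature-by-sample omics matrix from TSV
#'
#' Expects a header row of sample ids, a first column of feature ids, and
#' numeric cells. Duplicate feature or sample ids, ragged rows and
#' non-numeric cells are parse errors that name the offending row/column.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with feature rownames and sample colnames.
#' @seealso [write_omics()], [read_clinical()]
#' @export
read_omics <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "aesurv_path_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2L) abort(sprintf("'%s': need a feature-id column plus at least one sample", path))
  prob <- readr::problems(df)
  if (nrow(prob)) {
    abort(sprintf("'%s': malformed TSV (first issue: row %d, %s)", path,
                  prob$row[1L], prob$expected[1L]), class = "aesurv_parse_error")
  }
  feature_ids <- df[[1L]]
  sample_ids <- names(df)[-1L]
  if (anyDuplicated(feature_ids)) {
    abort(sprintf("'%s': duplicated feature id '%s'", path,
                  feature_ids[duplicated(feature_ids)][1L]),
          class = "aesurv_parse_error")
  }
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("'%s': duplicated sample id '%s'", path,
                  sample_ids[duplicated(sample_ids)][1L]),
          class = "aesurv_parse_error")
  }
  values <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(feature_ids, sample_ids))
  bad <- which(is.na(values) & !is.na(as.matrix(df[-1L])), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("'%s': non-numeric value at feature '%s', sample '%s'",
                  path, feature_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]),
          class = "aesurv_parse_error")
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    abort(sprintf("'%s': missing value at feature '%s', sample '%s'",
                  path, feature_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]),
          class = "aesurv_parse_error")
  }
  values
}

#' Write a feature-by-sample omics matrix to TSV
#'
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_omics <- function(m, path) {
  check_omics_matrix(m)
  df <- as_tibble(m, rownames = "feature_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample_id`, `time` (positive days) and `event` (0/1);
#' additional covariate columns are kept as-is, with `grade` promoted to an
#' ordered factor when present.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per sample.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "aesurv_path_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if ("grade" %in% names(df) && !is.ordered(df$grade)) {
    lev <- sort(unique(as.character(df$grade)))
    df$grade <- factor(df$grade, levels = lev, ordered = TRUE)
  }
  check_clinical(df)
  df
}

#' Write a clinical table to TSV
#' @param clinical A clinical tibble (see [read_clinical()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_clinical <- function(clinical, path) {
  check_clinical(clinical)
  out <- clinical
  out$grade <- as.character(out$grade)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Restrict omics matrices and the clinical table to their common samples
#'
#' Computes the intersection of sample ids across all sources and returns
#' every table restricted to it, columns/rows in one canonical (clinical)
#' order. Warns with the number of samples dropped per source.
#'
#' @param omics Named list of feature-by-sample matrices.
#' @param clinical Clinical tibble.
#' @return A list with elements `omics` (list of matrices) and `clinical`.
#' @export
align_samples <- function(omics, clinical) {
  if (!is.list(omics) || !length(omics)) abort("`omics` must be a non-empty list of matrices")
  purrr::walk(omics, check_omics_matrix)
  check_clinical(clinical)
  common <- Reduce(intersect, c(purrr::map(omics, colnames),
                                list(clinical$sample_id)))
  if (!length(common)) {
    abort("no samples are shared between the omics matrices and the clinical table",
          class = "aesurv_alignment_error")
  }
  # Canonical order: clinical order restricted to the intersection.
  common <- clinical$sample_id[clinical$sample_id %in% common]
  dropped <- c(purrr::map_int(omics, ~ ncol(.x) - length(common)),
               clinical = nrow(clinical) - length(common))
  if (any(dropped > 0)) {
    warn(sprintf("align_samples: dropped samples not shared by all sources (%s)",
                 paste(sprintf("%s: %d", names(dropped), dropped), collapse = ", ")))
  }
  list(omics = purrr::map(omics, ~ .x[, common, drop = FALSE]),
       clinical = clinical[match(common, clinical$sample_id), , drop = FALSE])
}

#' Filter features by median absolute deviation
#'
#' Retains exactly the features whose MAD (median of absolute deviations
#' from the feature median, unscaled) strictly exceeds `min_mad`; with the
#' default threshold 0 this drops constant features. Alternatively keeps the
#' `top_k` features ranked by MAD.
#'
#' @param m Feature-by-sample matrix.
#' @param min_mad Non-negative threshold; features with `MAD > min_mad` are
#'   kept. Ignored when `top_k` is given.
#' @param top_k Optional number of top-MAD features to keep.
#' @return The filtered matrix, feature order preserved.
#' @export
mad_filter <- function(m, min_mad = 0, top_k = NULL) {
  check_omics_matrix(m)
  check_scalar_num(min_mad, "min_mad", lower = 0)
  mads <- feature_mad(m)
  if (!is.null(top_k)) {
    check_scalar_num(top_k, "top_k", lower = 1, integer = TRUE)
    top_k <- min(top_k, nrow(m))
    keep_ids <- rownames(m)[order(-mads, rownames(m))][seq_len(top_k)]
    keep <- rownames(m) %in% keep_ids
  } else {
    keep <- mads > min_mad
  }
  if (!any(keep)) {
    abort(sprintf("mad_filter removed every feature at min_mad = %g; lower the threshold",
                  min_mad))
  }
  m[keep, , drop = FALSE]
}

feature_mad <- function(m) {
  med <- apply(m, 1L, median)
  apply(abs(m - med), 1L, median)
}

#' Fit a per-feature scaler on training data
#'
#' Robust mode stores the per-feature median and interquartile range
#' (linear-interpolation quantiles); standard mode stores the mean and the
#' population standard deviation. The fitted state is reused verbatim on
#' validation data via [apply_scaler()], mirroring the train-statistics-reuse
#' convention of two-cohort studies.
#'
#' @param train Feature-by-sample training matrix.
#' @param mode `"robust"` (median/IQR, default) or `"standard"` (mean/SD).
#' @return A list of class `scaler_state` with `center`, `spread`,
#'   `feature_ids` and `mode`.
#' @export
fit_scaler <- function(train, mode = c("robust", "standard")) {
  check_omics_matrix(train, "train")
  mode <- match.arg(mode)
  if (mode == "robust") {
    center <- apply(train, 1L, median)
    spread <- apply(train, 1L, function(x) {
      q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
      q[2L] - q[1L]
    })
  } else {
    center <- rowMeans(train)
    n <- ncol(train)
    spread <- sqrt(rowSums((train - center)^2) / n)  # population SD
  }
  zero <- spread <= 0
  if (any(zero)) {
    abort(sprintf("zero spread for feature(s) %s under %s scaling; mad_filter() first",
                  paste(head(rownames(train)[zero], 5L), collapse = ", "), mode),
          class = "aesurv_scaler_error")
  }
  structure(list(center = center, spread = spread,
                 feature_ids = rownames(train), mode = mode),
            class = "scaler_state")
}

#' Apply a fitted scaler to a matrix
#'
#' Restricts `m` to the scaler's features (in scaler order) and maps each
#' value to `(value - center) / spread` with the training statistics.
#'
#' @param m Feature-by-sample matrix containing at least the scaler features.
#' @param s A `scaler_state` from [fit_scaler()].
#' @return The scaled matrix, rows in scaler feature order.
#' @export
apply_scaler <- function(m, s) {
  check_omics_matrix(m)
  if (!inherits(s, "scaler_state")) abort("`s` must be a scaler_state")
  missing <- setdiff(s$feature_ids, rownames(m))
  if (length(missing)) {
    abort(sprintf("matrix is missing %d scaler feature(s): %s", length(missing),
                  paste(head(missing, 10L), collapse = ", ")),
          class = "aesurv_scaler_error")
  }
  m <- m[s$feature_ids, , drop = FALSE]
  (m - s$center) / s$spread
}

#' Squash features into the open unit interval
#'
#' Per-feature min-max map into `[epsilon, 1 - epsilon]`; constant features
#' map to 0.5. Keeps the cross-entropy reconstruction objective of the
#' autoencoder well-defined for arbitrary real-valued input features.
#'
#' @param m Feature-by-sample matrix.
#' @param epsilon Margin in `(0, 0.5)`.
#' @return Matrix of the same shape with values in `[epsilon, 1 - epsilon]`.
#' @export
squash_to_unit <- function(m, epsilon = 0.001) {
  check_omics_matrix(m)
  check_scalar_num(epsilon, "epsilon", lower = 0, upper = 0.5,
                   strict_lower = TRUE, strict_upper = TRUE)
  rng_min <- apply(m, 1L, min)
  rng_max <- apply(m, 1L, max)
  span <- rng_max - rng_min
  const <- span == 0
  span[const] <- 1  # avoid 0/0; constant rows overwritten below
  out <- epsilon + (1 - 2 * epsilon) * (m - rng_min) / span
  out <- pmin(pmax(out, epsilon), 1 - epsilon)  # guard one-ulp overshoot
  out[const, ] <- 0.5
  out
}

#' Preprocess a pair of training/validation omics matrices
#'
#' The two-step normalization used throughout the pipeline: MAD-based feature
#' filtering, then a scaler fitted on training data and reused on validation
#' data, optionally followed by [squash_to_unit()] for autoencoder input.
#'
#' @param train Feature-by-sample training matrix.
#' @param validation Optional validation matrix sharing the training features.
#' @param mad_threshold Strict MAD cutoff (see [mad_filter()]).
#' @param top_k Optional top-k-by-MAD alternative to the threshold.
#' @param scaler_mode `"robust"` or `"standard"`.
#' @param squash Logical; map scaled values into the open unit interval.
#' @param epsilon Margin for [squash_to_unit()].
#' @return A list with `train`, `validation` (or `NULL`) and the fitted
#'   `scaler`.
#' @export
preprocess_omics <- function(train, validation = NULL, mad_threshold = 0,
                             top_k = NULL, scaler_mode = c("robust", "standard"),
                             squash = TRUE, epsilon = 0.001) {
  scaler_mode <- match.arg(scaler_mode)
  train <- mad_filter(train, min_mad = mad_threshold, top_k = top_k)
  scaler <- fit_scaler(train, mode = scaler_mode)
  train_sc <- apply_scaler(train, scaler)
  val_sc <- NULL
  if (!is.null(validation)) {
    val_sc <- apply_scaler(validation, scaler)
  }
  if (squash) {
    train_sc <- squash_to_unit(train_sc, epsilon)
    if (!is.null(val_sc)) val_sc <- squash_to_unit(val_sc, epsilon)
  }
  list(train = train_sc, validation = val_sc, scaler = scaler)
}
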
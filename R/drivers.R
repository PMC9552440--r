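#' Identify methylation-driven genes between subtypes
#'
#' A gene is methylation-driven when (1) its gene-level methylation is
#' negatively correlated with its expression across all samples (Spearman
#' `r < r_threshold`, strict) and (2) its methylation differs between the
#' two subtypes (Wilcoxon rank-sum `p < p_threshold`, strict). Flagged genes
#' are classified `hypo_up` (lower methylation in the worst-prognosis
#' subtype, with correspondingly higher expression) or `hyper_down` by the
#' sign of the methylation difference.
#'
#' @param expr,meth Feature-by-sample matrices sharing gene ids (the
#'   intersection is used) and samples.
#' @param labels A `subtype_result`; the worst-prognosis subtype is the last
#'   factor level.
#' @param r_threshold Spearman threshold, default `-0.3` (strict `<`).
#' @param p_threshold Wilcoxon threshold, default `0.05` (strict `<`).
#' @return A tibble of class `driver_result`, one row per shared gene:
#'   `gene`, `spearman_r`, `wilcoxon_p`, `direction`
#'   (`hypo_up`/`hyper_down`/`none`), group means of methylation and
#'   expression.
#' @export
find_driver_genes <- function(expr, meth, labels, r_threshold = -0.3,
                              p_threshold = 0.05) {
  check_omics_matrix(expr, "expr")
  check_omics_matrix(meth, "meth")
  check_scalar_num(r_threshold, "r_threshold", lower = -1, upper = 1)
  check_scalar_num(p_threshold, "p_threshold", lower = 0, upper = 1)
  genes <- intersect(rownames(expr), rownames(meth))
  if (!length(genes)) abort("expr and meth share no gene ids")
  samples <- intersect(colnames(expr), colnames(meth))
  samples <- intersect(samples, labels$sample_id)
  if (length(samples) < 3L) abort("fewer than 3 samples shared across expr, meth and labels")
  inform(sprintf("find_driver_genes: %d shared genes, %d shared samples",
                 length(genes), length(samples)))
  e <- expr[genes, samples, drop = FALSE]
  m <- meth[genes, samples, drop = FALSE]
  grp <- labels_for_samples(labels, samples)
  lev <- levels(grp)
  if (length(lev) < 2L) abort("need at least two subtypes")
  best <- grp == lev[1L]           # G1: best prognosis
  worst <- grp == lev[length(lev)] # last level: worst prognosis

  n_skipped <- 0L
  rows <- purrr::map(seq_along(genes), function(i) {
    xe <- e[i, ]; xm <- m[i, ]
    if (sd(xe) == 0 || sd(xm) == 0) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    r <- cor(xm, xe, method = "spearman")
    p <- suppressWarnings(wilcox.test(xm[best], xm[worst], exact = FALSE)$p.value)
    mm1 <- mean(xm[best]); mm2 <- mean(xm[worst])
    direction <- if (r < r_threshold && p < p_threshold) {
      if (mm2 < mm1) "hypo_up" else "hyper_down"
    } else "none"
    tibble(gene = genes[i], spearman_r = r, wilcoxon_p = p,
           direction = direction,
           mean_meth_G1 = mm1, mean_meth_G2 = mm2,
           mean_expr_G1 = mean(xe[best]), mean_expr_G2 = mean(xe[worst]))
  })
  if (n_skipped > 0L) {
    warn(sprintf("skipped %d gene(s) with a constant methylation or expression vector",
                 n_skipped))
  }
  out <- bind_rows(rows)
  out$direction <- factor(out$direction, levels = c("hypo_up", "hyper_down", "none"))
  class(out) <- c("driver_result", class(out))
  attr(out, "thresholds") <- c(r = r_threshold, p = p_threshold)
  out
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: set name, description, then tab-separated gene ids.
#'
#' @param path GMT file path.
#' @return `read_gmt` returns a named list of character vectors (the
#'   description is kept in the `"description"` attribute of each set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path),
                                class = "aesurv_path_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) abort("malformed GMT line (need name, description, >= 1 gene)")
    genes <- unique(parts[-(1:2)])
    attr(genes, "description") <- parts[2L]
    genes
  })
  names(sets) <- vapply(lines, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1L]][1L], "")
  if (anyDuplicated(names(sets))) abort("duplicated gene-set names in GMT file")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors of gene ids.
#' @export
write_gmt <- function(sets, path) {
  if (!is.list(sets) || is.null(names(sets))) abort("`sets` must be a named list")
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test against gene-set collections
#'
#' One-sided hypergeometric tail probability `P(X >= overlap)` per set,
#' Benjamini-Hochberg adjusted across sets. Sets are intersected with the
#' universe first; the query must be a subset of the universe.
#'
#' @param query Character vector of genes of interest (e.g. driver genes).
#' @param collections Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector of all testable genes (typically the
#'   genes shared between the expression and methylation matrices).
#' @param alpha Significance threshold on the raw p-value (default 0.01).
#' @return A tibble sorted by p-value: `set_name`, `set_size`, `overlap`,
#'   `universe_size`, `p_value`, `adjusted_p`, `significant`.
#' @export
hypergeom_enrichment <- function(query, collections, universe, alpha = 0.01) {
  if (!length(universe)) abort("`universe` must be non-empty")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) {
    abort("`query` must be a subset of `universe`")
  }
  if (!is.list(collections) || is.null(names(collections))) {
    abort("`collections` must be a named list of gene sets")
  }
  check_scalar_num(alpha, "alpha", lower = 0, upper = 1)
  N <- length(universe); q <- length(query)
  rows <- purrr::imap(collections, function(genes, nm) {
    set <- intersect(unique(genes), universe)
    k <- length(set)
    ov <- length(intersect(set, query))
    p <- if (k == 0L) 1 else phyper(ov - 1L, k, N - k, q, lower.tail = FALSE)
    tibble(set_name = nm, set_size = k, overlap = ov,
           universe_size = N, p_value = p)
  })
  out <- bind_rows(rows)
  out$adjusted_p <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  arrange(out, .data$p_value, .data$set_name)
}
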
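#' Remove genes with low average expression
#'
#' Log2 intensities of expressed and unexpressed genes typically form a
#' bimodal distribution; genes whose mean log2 intensity across all samples
#' falls at or below the threshold mostly contribute noise and are removed
#' before any axis is derived. The boundary is strict: a gene is retained
#' only if its mean is strictly greater than `threshold`.
#'
#' @param ds An `expr_dataset`.
#' @param threshold Log2-intensity cutoff; default 4.5, the valley between
#'   the two modes of typical two-color microarray intensity distributions.
#' @return The filtered `expr_dataset` (same samples, fewer genes).
#' @export
filter_low_expression <- function(ds, threshold = 4.5) {
  stopifnot(is.finite(threshold) || threshold == -Inf)
  m <- rowMeans(ds$values)
  keep <- m > threshold
  if (!any(keep))
    stop("all genes fall below the expression threshold (", threshold, ")")
  message("filter_low_expression: retained ", sum(keep), " of ", length(keep),
          " genes (threshold ", threshold, ")")
  ds[keep, ]
}

#' Fit a per-gene standardizer
#'
#' Computes per-gene mean and standard deviation (denominator n - 1) on a
#' training subset. Genes with zero variance are dropped (they carry no
#' directional information) with a warning listing their IDs. The returned
#' object is reused to place any other dataset in the same standardized
#' coordinates before projection onto an axis derived from this training
#' subset.
#'
#' @param ds An `expr_dataset` with at least two samples, typically already
#'   filtered with [filter_low_expression()].
#' @param source_tag Label recording which subset the statistics come from.
#' @return A list of class `standardizer` with elements `gene_ids`, `mean`,
#'   `sd` and `source_tag`.
#' @export
fit_standardizer <- function(ds, source_tag = "") {
  if (ncol(ds$values) < 2L)
    stop("at least 2 samples are required to fit a standardizer")
  m <- rowMeans(ds$values)
  n <- ncol(ds$values)
  s <- sqrt(rowSums((ds$values - m)^2) / (n - 1))
  zero <- s < 1e-12
  if (any(zero)) {
    ids <- gene_ids(ds)[zero]
    warning("dropping ", sum(zero), " zero-variance gene(s): ",
            paste(utils::head(ids, 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "")
  }
  structure(list(gene_ids = gene_ids(ds)[!zero],
                 mean = unname(m[!zero]),
                 sd = unname(s[!zero]),
                 source_tag = source_tag),
            class = "standardizer")
}

#' @export
print.standardizer <- function(x, ...) {
  cat("standardizer: ", length(x$gene_ids), " genes",
      if (nzchar(x$source_tag)) paste0(" (fit on ", x$source_tag, ")"),
      "\n", sep = "")
  invisible(x)
}

# restrict a standardizer to a gene subset, preserving the given order
subset_standardizer <- function(st, genes) {
  idx <- match(genes, st$gene_ids)
  if (anyNA(idx)) stop("gene(s) absent from standardizer")
  structure(list(gene_ids = st$gene_ids[idx], mean = st$mean[idx],
                 sd = st$sd[idx], source_tag = st$source_tag),
            class = "standardizer")
}

#' Standardize a dataset with previously fitted statistics
#'
#' Centers and scales each gene with the training mean and standard
#' deviation held by `st`. By default every gene of the standardizer must be
#' present in `ds`; with `partial = TRUE` the intersection is used as long
#' as it covers at least `min_overlap` of the standardizer's genes (the
#' behaviour used when projecting datasets with a different post-filter gene
#' complement).
#'
#' @param ds An `expr_dataset`.
#' @param st A `standardizer` from [fit_standardizer()].
#' @param partial Allow a partial gene overlap.
#' @param min_overlap Minimum tolerated fraction of the standardizer's genes
#'   present in `ds` when `partial = TRUE`; default 0.9.
#' @return An `expr_dataset` of standardized values restricted to the shared
#'   genes, ordered as in `st`.
#' @export
apply_standardizer <- function(ds, st, partial = FALSE, min_overlap = 0.9) {
  present <- st$gene_ids %in% gene_ids(ds)
  frac <- mean(present)
  if (!all(present)) {
    if (!partial)
      stop("gene(s) of the standardizer absent from dataset: ",
           paste(utils::head(st$gene_ids[!present], 5), collapse = ", "),
           " (", sum(!present), " missing)")
    if (frac < min_overlap)
      stop(sprintf(
        "gene overlap %.1f%% is below the configured floor of %.1f%%",
        100 * frac, 100 * min_overlap))
  }
  st_sub <- if (all(present)) st else
    subset_standardizer(st, st$gene_ids[present])
  z <- (ds$values[st_sub$gene_ids, , drop = FALSE] - st_sub$mean) / st_sub$sd
  expression_dataset(z, ds$samples)
}
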
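#' Expression dataset container
#'
#' Bundles a genes x samples matrix of log2 intensities with a per-sample
#' metadata sheet, in the style of limma's `EList`. The metadata sheet must
#' contain the columns `sample_id`, `genotype`, `treatment` (one of
#' `"control"`, `"heat"`, `"recovery"`), `t_dev` (hours post
#' age-synchronization), `t_heat` (hours at the stress temperature), `t_rec`
#' (hours of recovery) and `split` (`"train"`, `"test"` or `"unassigned"`).
#'
#' @param values Numeric matrix of log2 intensities, genes in rows (rownames
#'   are gene identifiers), samples in columns.
#' @param samples Data frame of per-sample metadata, one row per column of
#'   `values`, in the same order.
#' @return An object of class `expr_dataset` with elements `values` and
#'   `samples`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
#' meta <- data.frame(sample_id = c("a", "b"), genotype = "N2",
#'                    treatment = "control", t_dev = c(46, 48),
#'                    t_heat = 0, t_rec = 0, split = "train")
#' ds <- expression_dataset(m, meta)
#' dim(ds)
#' @export
expression_dataset <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("'values' must have gene identifiers as rownames")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  ds <- structure(list(values = values, samples = samples),
                  class = "expr_dataset")
  validate_expression_dataset(ds)
  ds
}

required_sample_columns <- function() {
  c("sample_id", "genotype", "treatment", "t_dev", "t_heat", "t_rec", "split")
}

validate_expression_dataset <- function(ds) {
  values <- ds$values
  samples <- ds$samples
  missing_cols <- setdiff(required_sample_columns(), names(samples))
  if (length(missing_cols) > 0L)
    stop("sample metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("number of metadata rows (", nrow(samples),
         ") does not match number of sample columns (", ncol(values), ")")
  gene_ids <- rownames(values)
  if (anyDuplicated(gene_ids))
    stop("duplicated gene identifier(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)])[1:5], collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample identifier(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), as.character(samples$sample_id)))
    stop("column names of 'values' do not match metadata sample_id order")
  bad_treat <- setdiff(unique(samples$treatment),
                       c("control", "heat", "recovery"))
  if (length(bad_treat) > 0L)
    stop("invalid treatment value(s): ", paste(bad_treat, collapse = ", "))
  bad_split <- setdiff(unique(samples$split),
                       c("train", "test", "unassigned"))
  if (length(bad_split) > 0L)
    stop("invalid split value(s): ", paste(bad_split, collapse = ", "))
  ctrl <- samples$treatment == "control"
  if (any(ctrl & (samples$t_heat != 0 | samples$t_rec != 0)))
    stop("control samples must have t_heat = 0 and t_rec = 0")
  heat <- samples$treatment == "heat"
  if (any(heat & (samples$t_heat <= 0 | samples$t_rec != 0)))
    stop("heat samples must have t_heat > 0 and t_rec = 0")
  rec <- samples$treatment == "recovery"
  if (any(rec & (samples$t_heat <= 0 | samples$t_rec < 0)))
    stop("recovery samples must have t_heat > 0 and t_rec >= 0")
  invisible(ds)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' @export
print.expr_dataset <- function(x, ...) {
  cat("expr_dataset: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  tab <- table(x$samples$treatment)
  cat("treatments:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression dataset
#'
#' @param x An `expr_dataset`.
#' @param i Gene index (character, logical or integer).
#' @param j Sample index (character sample IDs, logical or integer).
#' @param ... Unused.
#' @return An `expr_dataset` restricted to the selected genes and samples.
#' @export
`[.expr_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  values <- x$values[i, j, drop = FALSE]
  samples <- x$samples[j, , drop = FALSE]
  rownames(samples) <- NULL
  expression_dataset(values, samples)
}

#' Gene identifiers of an expression dataset
#'
#' @param ds An `expr_dataset`.
#' @return Character vector of gene IDs, in matrix row order.
#' @export
gene_ids <- function(ds) rownames(ds$values)

#' Select samples of an expression dataset by metadata predicate
#'
#' Convenience wrapper used throughout the pipeline to pull out training and
#' testing subsets, e.g. the unperturbed training samples an axis is derived
#' from.
#'
#' @param ds An `expr_dataset`.
#' @param ... Logical expressions evaluated in the metadata sheet (as in
#'   `subset()`), combined with AND.
#' @return An `expr_dataset` containing the matching samples.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, n_genotypes = 4))
#' ctrl_train <- select_samples(sim$dataset, treatment == "control",
#'                              split == "train")
#' @export
select_samples <- function(ds, ...) {
  conds <- eval(substitute(alist(...)))
  keep <- rep(TRUE, nrow(ds$samples))
  for (cond in conds) {
    v <- eval(cond, ds$samples, parent.frame())
    keep <- keep & v
  }
  if (!any(keep)) stop("no samples match the given condition(s)")
  ds[, which(keep)]
}
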
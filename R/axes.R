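#' Principal axes of a standardized expression dataset
#'
#' Runs a principal component analysis (via [stats::prcomp()], i.e. singular
#' value decomposition) on a dataset that has already been centered and
#' scaled per gene with [apply_standardizer()]. Gene-space loadings are
#' orthonormal and ordered by decreasing variance explained; because the
#' genes are centered across samples, at most `n_samples - 1` components
#' carry variance.
#'
#' @param ds_std Standardized `expr_dataset` (output of
#'   [apply_standardizer()]).
#' @param st The `standardizer` that produced `ds_std`; carried along so
#'   that axes built from these components can standardize new data.
#' @param k Number of components to retain; defaults to all available.
#' @return A list of class `principal_axes` with `loadings` (genes x k),
#'   `scores` (samples x k, the training projections), `variance_explained`
#'   (fraction of total training variance per component), `gene_ids` and
#'   `standardizer`.
#' @export
fit_principal_axes <- function(ds_std, st, k = NULL) {
  X <- ds_std$values
  pr <- stats::prcomp(t(X), center = FALSE, scale. = FALSE)
  available <- sum(pr$sdev > 1e-9 * pr$sdev[1L])
  if (is.null(k)) k <- min(available, ncol(X) - 1L)
  if (k > available)
    stop("k = ", k, " exceeds the rank of the data (", available,
         " non-degenerate components)")
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 scores = pr$x[, seq_len(k), drop = FALSE],
                 variance_explained = ve[seq_len(k)],
                 gene_ids = gene_ids(ds_std),
                 standardizer = st),
            class = "principal_axes")
}

new_stress_axis <- function(loadings, gene_ids, standardizer, component_index,
                            variance_explained, name = "custom",
                            orientation_covariate = NA_character_,
                            confound_overlap = NA_real_,
                            raw_loadings = NULL) {
  loadings <- as.numeric(loadings)
  names(loadings) <- gene_ids
  structure(list(name = name, loadings = loadings, gene_ids = gene_ids,
                 standardizer = standardizer,
                 component_index = component_index,
                 orientation_covariate = orientation_covariate,
                 variance_explained = variance_explained,
                 confound_overlap = confound_overlap,
                 raw_loadings = raw_loadings),
            class = "stress_axis")
}

#' @export
print.stress_axis <- function(x, ...) {
  cat("stress_axis '", x$name, "': ", length(x$loadings), " genes, from PC",
      x$component_index, sep = "")
  if (!is.na(x$variance_explained))
    cat(sprintf(" (%.1f%% of training variance)", 100 * x$variance_explained))
  if (!is.na(x$confound_overlap))
    cat(sprintf("; confound overlap %.3f", x$confound_overlap))
  cat("\n")
  invisible(x)
}

#' Select the component carrying the variation of interest
#'
#' In this class of time-series expression data the first component usually
#' absorbs technical array-to-array intensity variation, and the component
#' of interest (developmental age, or stress-response state) is the second
#' one. `mode = "fixed_second"` encodes that choice; `mode =
#' "max_association"` instead picks the component whose training projections
#' have the largest absolute Spearman correlation with a covariate, and
#' warns when that is not component 2.
#'
#' @param pa A `principal_axes` object.
#' @param covariate Per-training-sample covariate values (e.g. hours of
#'   development or stress exposure); required for `"max_association"`.
#' @param mode `"fixed_second"` (default) or `"max_association"`.
#' @param name Name to give the resulting axis.
#' @return A `stress_axis` (not yet orthogonalized or oriented).
#' @export
select_component <- function(pa, covariate = NULL,
                             mode = c("fixed_second", "max_association"),
                             name = "custom") {
  mode <- match.arg(mode)
  k <- ncol(pa$loadings)
  if (k < 2L) stop("at least 2 principal components are required")
  if (mode == "fixed_second") {
    idx <- 2L
  } else {
    if (is.null(covariate))
      stop("'covariate' is required for mode = 'max_association'")
    if (length(covariate) != nrow(pa$scores))
      stop("covariate length does not match number of training samples")
    if (length(unique(covariate)) < 2L)
      stop("covariate is constant; association cannot be ranked")
    rho <- apply(pa$scores, 2L, function(s)
      abs(stats::cor(s, covariate, method = "spearman")))
    idx <- as.integer(which.max(rho))
    if (idx != 2L)
      warning("component most associated with the covariate is PC", idx,
              ", not PC2")
  }
  new_stress_axis(pa$loadings[, idx], pa$gene_ids, pa$standardizer,
                  component_index = idx,
                  variance_explained = pa$variance_explained[idx],
                  name = name)
}

# unit-normalize a loading vector over a gene subset
renormalize_loadings <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) stop("cannot normalize a zero loading vector")
  v / nrm
}

#' Remove a confounding axis by orthogonalization
#'
#' Given a candidate axis (e.g. the leading stress-data component, which
#' still mixes stress response with development) and a confound axis (e.g.
#' the developmental axis), forms the Gram-Schmidt residual
#' `candidate - (candidate . confound) confound`, re-normalized to unit
#' length. Both axes are first restricted to their shared gene set and
#' re-normalized there; the scalar overlap is recorded in the result's
#' `confound_overlap` field and the pre-orthogonalization loadings in
#' `raw_loadings`.
#'
#' @param candidate,confound `stress_axis` objects.
#' @return A `stress_axis` orthogonal to `confound` (dot product zero to
#'   within 1e-9), carrying the candidate's standardizer restricted to the
#'   shared genes.
#' @export
orthogonalize <- function(candidate, confound) {
  common <- intersect(candidate$gene_ids, confound$gene_ids)
  if (length(common) < 2L)
    stop("candidate and confound axes share fewer than 2 genes")
  v <- renormalize_loadings(candidate$loadings[common])
  d <- renormalize_loadings(confound$loadings[common])
  overlap <- sum(v * d)
  resid <- v - overlap * d
  nrm <- sqrt(sum(resid^2))
  if (nrm < 1e-8)
    stop("axis degenerate after confound removal (residual norm ", nrm, ")")
  new_stress_axis(resid / nrm, common,
                  subset_standardizer(candidate$standardizer, common),
                  component_index = candidate$component_index,
                  variance_explained = candidate$variance_explained,
                  name = candidate$name,
                  confound_overlap = overlap,
                  raw_loadings = stats::setNames(v, common))
}

#' Orient an axis against a covariate
#'
#' PCA loadings are defined only up to sign. This resolves the ambiguity by
#' projecting an orientation dataset onto the axis and flipping the
#' loadings, if needed, so that scores increase with the covariate
#' (developmental time for a developmental axis, exposure duration for a
#' stress axis) or, with `covariate = "treatment"`, so that the mean score
#' of heat samples exceeds the mean score of control samples (the contrast
#' used for genotype axes, which have no time covariate). Orientation is
#' idempotent: an already-oriented axis is returned unchanged.
#'
#' @param axis A `stress_axis`.
#' @param ds `expr_dataset` used to compute orientation projections
#'   (typically the axis's training set, or a combined control + heat set
#'   for the treatment contrast).
#' @param covariate Name of a numeric metadata column (`"t_dev"`,
#'   `"t_heat"`, ...) or `"treatment"` for the control-vs-heat contrast.
#' @return The oriented `stress_axis`, with `orientation_covariate`
#'   recorded. If the absolute rank correlation with the covariate is below
#'   0.05 a warning is emitted and the sign is left unchanged.
#' @export
orient_axis <- function(axis, ds, covariate) {
  proj <- project(ds, axis)
  if (covariate == "treatment") {
    if (!all(c("control", "heat") %in% proj$treatment))
      stop("treatment contrast orientation requires control and heat samples")
    x <- as.numeric(proj$treatment == "heat")
  } else {
    if (!covariate %in% names(proj))
      stop("covariate '", covariate, "' not found in sample metadata")
    x <- proj[[covariate]]
  }
  rho <- suppressWarnings(stats::cor(proj$score, x, method = "spearman"))
  if (is.na(rho) || abs(rho) < 0.05) {
    warning("axis '", axis$name, "' shows no clear association with '",
            covariate, "' (rho = ", signif(rho, 3), "); sign left unchanged")
    axis$orientation_covariate <- covariate
    return(axis)
  }
  if (rho < 0) axis$loadings <- -axis$loadings
  axis$orientation_covariate <- covariate
  axis
}

#' Project samples onto an axis
#'
#' Each sample's log2 expression profile is placed in the axis's training
#' coordinates (centered and scaled with the training statistics carried by
#' the axis) and its score is the inner product with the unit loading
#' vector. If the dataset's gene complement differs from the axis's, the
#' shared genes are used and the loadings are re-normalized over the
#' intersection (which must cover at least `min_overlap` of the axis's
#' genes). The mean profile of the axis's training set scores exactly zero.
#'
#' @param ds An `expr_dataset` of raw (unstandardized) log2 values.
#' @param axis A `stress_axis`.
#' @param min_overlap Minimum tolerated fraction of the axis's genes present
#'   in `ds`.
#' @return A data frame of class `projection_table` with the sample
#'   metadata columns and a `score` column; the axis name is stored in the
#'   `"axis_name"` attribute.
#' @export
project <- function(ds, axis, min_overlap = 0.9) {
  z <- apply_standardizer(ds, axis$standardizer, partial = TRUE,
                          min_overlap = min_overlap)
  w <- renormalize_loadings(axis$loadings[gene_ids(z)])
  score <- as.numeric(crossprod(z$values, w))
  out <- cbind(ds$samples[, required_sample_columns(), drop = FALSE],
               score = score)
  rownames(out) <- NULL
  attr(out, "axis_name") <- axis$name
  class(out) <- c("projection_table", "data.frame")
  out
}

#' Derive a confound axis and a confound-free axis from paired training sets
#'
#' Implements the full two-step axis inference used for the developmental /
#' heat-stress pair (D, H) and for the genotype pair (GD, GH):
#'
#' 1. center and scale the control training set, run PCA, select the
#'    component of interest and orient it => the confound axis (D or GD);
#' 2. center and scale the stress training set, run PCA, select the
#'    component of interest => the raw stress axis;
#' 3. remove the confound by Gram-Schmidt orthogonalization and re-orient
#'    => the stress axis (H or GH), orthogonal to the confound.
#'
#' @param control_train `expr_dataset` of unperturbed training samples.
#' @param stress_train `expr_dataset` of stressed training samples.
#' @param config List of options: `component_mode` (`"fixed_second"` or
#'   `"max_association"`), `k` (components to fit, default 5),
#'   `control_covariate` (orientation/selection covariate for the confound
#'   axis, default `"t_dev"`; use `"treatment"` for genotype axes),
#'   `stress_covariate` (default `"t_heat"`; use `"treatment"` for genotype
#'   axes), `orientation_data` (an `expr_dataset` with both control and heat
#'   samples, required when a covariate is `"treatment"`), and `names`
#'   (length-2 character, default `c("D", "H")`).
#' @return Named list of two `stress_axis` objects (confound axis first),
#'   with an attribute `"provenance"` recording component indices, the
#'   confound overlap scalar, and training sample counts.
#' @export
derive_axis_pair <- function(control_train, stress_train, config = list()) {
  defaults <- list(component_mode = "fixed_second", k = 5L,
                   control_covariate = "t_dev", stress_covariate = "t_heat",
                   orientation_data = NULL, names = c("D", "H"))
  cfg <- utils::modifyList(defaults, config)

  orientation_ds <- function(covariate, own_train) {
    if (covariate == "treatment") {
      if (is.null(cfg$orientation_data))
        stop("config$orientation_data is required for treatment-contrast ",
             "orientation")
      cfg$orientation_data
    } else own_train
  }
  covariate_values <- function(ds, covariate) {
    if (is.null(covariate) || covariate == "treatment") NULL
    else ds$samples[[covariate]]
  }

  st_c <- fit_standardizer(control_train, source_tag = paste0(cfg$names[1L], "_train"))
  kc <- min(cfg$k, ncol(control_train$values) - 1L)
  pa_c <- fit_principal_axes(apply_standardizer(control_train, st_c), st_c, k = kc)
  confound <- select_component(pa_c,
                               covariate = covariate_values(control_train,
                                                            cfg$control_covariate),
                               mode = cfg$component_mode, name = cfg$names[1L])
  confound <- orient_axis(confound,
                          orientation_ds(cfg$control_covariate, control_train),
                          cfg$control_covariate)

  st_s <- fit_standardizer(stress_train, source_tag = paste0(cfg$names[2L], "_train"))
  ks <- min(cfg$k, ncol(stress_train$values) - 1L)
  pa_s <- fit_principal_axes(apply_standardizer(stress_train, st_s), st_s, k = ks)
  raw_stress <- select_component(pa_s,
                                 covariate = covariate_values(stress_train,
                                                              cfg$stress_covariate),
                                 mode = cfg$component_mode, name = cfg$names[2L])
  stress <- orthogonalize(raw_stress, confound)
  stress <- orient_axis(stress,
                        orientation_ds(cfg$stress_covariate, stress_train),
                        cfg$stress_covariate)

  out <- stats::setNames(list(confound, stress), cfg$names)
  attr(out, "provenance") <- list(
    confound_component = confound$component_index,
    stress_component = stress$component_index,
    confound_overlap = stress$confound_overlap,
    n_control_train = ncol(control_train$values),
    n_stress_train = ncol(stress_train$values),
    component_mode = cfg$component_mode)
  out
}
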
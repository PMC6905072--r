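#' Genotype-level resilience scores from axis projections
#'
#' Aggregates per-sample projections (typically on the genetic heat-stress
#' axis) to one score per genotype and condition: `gh_recovery` is the mean
#' score of that genotype's recovery samples — the transcriptome resilience
#' read-out (high = still far from the unperturbed state, i.e. low
#' resilience) — and `gh_heat` the mean score of its heat samples.
#' Genotypes lacking a condition get `NA` for that field.
#'
#' @param proj A `projection_table` from [project()].
#' @return A data frame of class `resilience_scores` with columns
#'   `genotype`, `gh_recovery`, `gh_heat`, `n_recovery`, `n_heat`.
#' @export
score_resilience <- function(proj) {
  if (nrow(proj) == 0L) stop("empty projection table")
  genotypes <- unique(proj$genotype)
  agg <- function(g, treat) proj$score[proj$genotype == g & proj$treatment == treat]
  out <- data.frame(
    genotype = genotypes,
    gh_recovery = vapply(genotypes, function(g) {
      s <- agg(g, "recovery"); if (length(s)) mean(s) else NA_real_
    }, numeric(1)),
    gh_heat = vapply(genotypes, function(g) {
      s <- agg(g, "heat"); if (length(s)) mean(s) else NA_real_
    }, numeric(1)),
    n_recovery = vapply(genotypes, function(g) length(agg(g, "recovery")), integer(1)),
    n_heat = vapply(genotypes, function(g) length(agg(g, "heat")), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "axis_name") <- attr(proj, "axis_name")
  class(out) <- c("resilience_scores", "data.frame")
  out
}

#' Null distribution of projection SDs over random sample subsets
#'
#' Asks whether genotype-to-genotype scatter of projections exceeds what
#' replicate measurements of a single genotype would show: draws `n_reps`
#' random subsets (without replacement) of size `n_subset` from a pool of
#' projection scores, records each subset's standard deviation, and ranks a
#' reference SD (e.g. the SD of N2 replicate projections) within that
#' distribution.
#'
#' @param scores Numeric vector of projection scores (one treatment's
#'   pool), or a `projection_table` combined with `treatment`.
#' @param n_subset Subset size, matching the number of reference replicates.
#' @param n_reps Number of random subsets; default 5000.
#' @param seed Integer seed; the distribution is fully reproducible from it.
#' @param reference_sd Optional reference SD to rank within the null.
#' @param treatment If `scores` is a `projection_table`, the treatment whose
#'   scores form the pool.
#' @return A list of class `subset_sd_report` with `treatment`, `n_subset`,
#'   `n_reps`, `sd_distribution`, `reference_sd` and `reference_percentile`
#'   (percentage of subset SDs at or below the reference).
#' @export
subset_sd_distribution <- function(scores, n_subset, n_reps = 5000L,
                                   seed = NULL, reference_sd = NULL,
                                   treatment = NULL) {
  if (inherits(scores, "projection_table")) {
    if (is.null(treatment))
      stop("'treatment' is required when passing a projection table")
    pool <- scores$score[scores$treatment == treatment]
  } else {
    pool <- as.numeric(scores)
  }
  if (n_subset < 2L) stop("n_subset must be >= 2")
  if (length(pool) < n_subset)
    stop("pool of ", length(pool), " scores is smaller than n_subset = ",
         n_subset)
  if (!is.null(seed)) set.seed(seed)
  sds <- vapply(seq_len(n_reps),
                function(i) stats::sd(pool[sample.int(length(pool), n_subset)]),
                numeric(1))
  pct <- if (is.null(reference_sd)) NA_real_ else 100 * mean(sds <= reference_sd)
  structure(list(treatment = if (is.null(treatment)) NA_character_ else treatment,
                 n_subset = as.integer(n_subset),
                 n_reps = as.integer(n_reps),
                 sd_distribution = sds,
                 reference_sd = if (is.null(reference_sd)) NA_real_ else reference_sd,
                 reference_percentile = pct),
            class = "subset_sd_report")
}

#' @export
print.subset_sd_report <- function(x, ...) {
  cat("subset_sd_report: ", x$n_reps, " subsets of size ", x$n_subset,
      if (!is.na(x$treatment)) paste0(" (", x$treatment, ")"), "\n", sep = "")
  cat(sprintf("  subset SD: median %.4g [%.4g, %.4g]\n",
              stats::median(x$sd_distribution),
              stats::quantile(x$sd_distribution, 0.025),
              stats::quantile(x$sd_distribution, 0.975)))
  if (!is.na(x$reference_sd))
    cat(sprintf("  reference SD %.4g at percentile %.1f\n",
                x$reference_sd, x$reference_percentile))
  invisible(x)
}
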
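#' Spearman rank correlation with small-sample exact p-value
#'
#' Computes the Spearman correlation on average ranks (midranks for ties).
#' For n of at most 10 the two-sided p-value is obtained by exhaustive
#' enumeration of all permutations of one margin (a compiled routine);
#' for larger n the usual t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with n - 2 degrees of freedom is
#' used. Pairs with a missing value are dropped.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list of class `correlation_result` with `rho`, `p`, `n` and
#'   `method` (`"exact"` or `"t-approximation"`).
#' @examples
#' spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))  # rho 0.8, exact p 1/3
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs are required")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("cannot rank-correlate a constant vector")
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    p <- spearman_perm_pvalue(rx, ry)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  structure(list(rho = rho, p = p, n = n, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.3g (n = %d, %s)\n",
              x$rho, x$p, x$n, x$method))
  invisible(x)
}

#' Top-contributing genes of an axis
#'
#' Ranks genes by the absolute value of their loading and returns the top
#' fraction (default 5%), each labeled `"up"` (positive loading: expression
#' rises along the axis relative to baseline) or `"down"`. Ties at the
#' cutoff are broken by gene ID order. `tail` restricts the ranking to one
#' sign.
#'
#' @param axis A `stress_axis`.
#' @param fraction Fraction of genes to return, in (0, 1); default 0.05.
#' @param tail `"abs"` (default), `"up"` or `"down"`.
#' @return A data frame with columns `gene_id`, `loading`, `direction`,
#'   ordered by decreasing `|loading|`.
#' @export
top_contributors <- function(axis, fraction = 0.05,
                             tail = c("abs", "up", "down")) {
  tail <- match.arg(tail)
  stopifnot(fraction > 0, fraction < 1)
  l <- axis$loadings
  l <- switch(tail, abs = l, up = l[l > 0], down = l[l < 0])
  n_top <- ceiling(fraction * length(axis$loadings))
  ord <- order(-abs(l), names(l))
  sel <- ord[seq_len(min(n_top, length(l)))]
  data.frame(gene_id = names(l)[sel], loading = unname(l[sel]),
             direction = ifelse(l[sel] < 0, "down", "up"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# upper-tail hypergeometric probability of an overlap at least as large as
# observed, P(X >= k) with K marked among N, draws of size n
hypergeom_upper <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests whether a query gene list (e.g. the top contributors of an axis)
#' overlaps each annotation set more than expected from random draws out of
#' the universe. Each set is intersected with the universe before testing;
#' p-values are upper-tail hypergeometric probabilities, Bonferroni
#' multiplied by the number of sets tested. A set passes the reporting
#' filter when the corrected p is below 0.05, the (universe-restricted) set
#' has more than 3 members, and the overlap exceeds 2 genes.
#'
#' @param query Character vector of query gene IDs (must be a subset of
#'   `universe`).
#' @param sets A `gene_set_collection` or named list of character vectors.
#' @param universe Character vector of background gene IDs (e.g. all genes
#'   surviving the expression filter).
#' @return A data frame of class `enrichment_table` with columns
#'   `set_name`, `set_size`, `overlap`, `p`, `p_bonferroni`,
#'   `passes_filter`, ordered by `p`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0L) stop("empty query gene list")
  if (!all(query %in% universe))
    stop("query contains gene(s) outside the universe")
  N <- length(universe)
  n <- length(query)
  m <- length(sets)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- if (K == 0L) 1 else hypergeom_upper(k, K, N, n)
    data.frame(set_name = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * m)
  out$passes_filter <- out$p_bonferroni < 0.05 & out$set_size > 3 &
    out$overlap > 2
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Overlap test between two gene lists
#'
#' Same hypergeometric machinery as [hypergeometric_enrichment()] but for a
#' single externally supplied reference list (an eQTL gene list, a
#' polymorphism class, ...) with the stricter reporting filter used for
#' such comparisons: Bonferroni-corrected p below 0.001 (the multiplier is
#' the number of comparisons in the wider analysis, `n_tests`) and an
#' overlap of more than 10 genes.
#'
#' @param query,reference Character vectors of gene IDs; both are
#'   intersected with `universe` (the query must lie within it).
#' @param universe Character vector of background gene IDs.
#' @param n_tests Bonferroni multiplier; default 1.
#' @return A one-row data frame with the same columns as
#'   [hypergeometric_enrichment()].
#' @export
overlap_test <- function(query, reference, universe, n_tests = 1L) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0L) stop("empty query gene list")
  if (!all(query %in% universe))
    stop("query contains gene(s) outside the universe")
  reference <- intersect(unique(reference), universe)
  K <- length(reference)
  k <- length(intersect(reference, query))
  p <- if (K == 0L) 1 else hypergeom_upper(k, K, length(universe), length(query))
  p_bonf <- min(1, p * n_tests)
  out <- data.frame(set_name = "reference", set_size = K, overlap = k,
                    p = p, p_bonferroni = p_bonf,
                    passes_filter = p_bonf < 0.001 & k > 10,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_table", "data.frame")
  out
}
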
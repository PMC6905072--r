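#' Per-genotype thermotolerance from lifespan data
#'
#' Thermotolerance is operationalized as the ratio of the mean lifespan of
#' the heat-stressed arm to the mean lifespan of the control arm
#' (`direction = "heat_over_control"`, the default); values near 1 indicate
#' genotypes whose survival is barely affected by the stress. The inverse
#' ratio is available via `direction = "control_over_heat"`.
#'
#' @param surv A [survival_table()].
#' @param direction Ratio orientation; see above.
#' @return A data frame of class `thermotolerance_table` with columns
#'   `genotype`, `mean_control`, `mean_heat`, `ratio`, `n_control`,
#'   `n_heat`. Genotypes missing one arm are skipped with a warning.
#' @export
thermotolerance <- function(surv,
                            direction = c("heat_over_control",
                                          "control_over_heat")) {
  direction <- match.arg(direction)
  genotypes <- unique(surv$genotype)
  rows <- list()
  skipped <- character(0)
  for (g in genotypes) {
    ctrl <- surv$day[surv$genotype == g & surv$treatment == "control" &
                       surv$status == 1L]
    heat <- surv$day[surv$genotype == g & surv$treatment == "heat" &
                       surv$status == 1L]
    if (length(ctrl) == 0L || length(heat) == 0L) {
      skipped <- c(skipped, g)
      next
    }
    ratio <- if (direction == "heat_over_control")
      mean(heat) / mean(ctrl) else mean(ctrl) / mean(heat)
    rows[[g]] <- data.frame(genotype = g, mean_control = mean(ctrl),
                            mean_heat = mean(heat), ratio = ratio,
                            n_control = length(ctrl), n_heat = length(heat),
                            stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L)
    warning("genotype(s) missing an arm skipped: ",
            paste(skipped, collapse = ", "))
  if (length(rows) == 0L) stop("no genotype has events in both arms")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "direction") <- direction
  class(out) <- c("thermotolerance_table", "data.frame")
  out
}

#' Two-sample logrank test
#'
#' Standard logrank comparison of two survival curves: at each distinct
#' event time the observed number of events in arm A is compared with its
#' expectation under the null of identical hazards, with the hypergeometric
#' variance accounting for ties; the squared standardized sum is referred to
#' a chi-squared distribution with one degree of freedom.
#'
#' @param time_a,time_b Event/censoring times of the two arms.
#' @param status_a,status_b Event indicators (1 = event, 0 = censored);
#'   default all events.
#' @return A list with `statistic` (chi-squared, 1 df), `p`, `observed`,
#'   `expected` (arm A) and `variance`.
#' @examples
#' logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))$statistic  # 49/17
#' @export
logrank_test <- function(time_a, status_a = rep(1L, length(time_a)),
                         time_b, status_b = rep(1L, length(time_b))) {
  stopifnot(length(time_a) == length(status_a),
            length(time_b) == length(status_b))
  if (sum(status_a) + sum(status_b) == 0L)
    stop("no events in either arm")
  if (sum(status_a) == 0L || sum(status_b) == 0L)
    stop("each arm must contain at least one event")
  time <- c(time_a, time_b)
  status <- c(status_a, status_b)
  arm_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  event_times <- sort(unique(time[status == 1L]))
  O <- E <- V <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & arm_a)
    d <- sum(time == t & status == 1L)
    d_a <- sum(time == t & status == 1L & arm_a)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1L)
      V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  if (V <= 0) {
    statistic <- 0
    p <- 1
  } else {
    statistic <- (O - E)^2 / V
    p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  }
  list(statistic = statistic, p = p, observed = O, expected = E, variance = V)
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]);
#' adjusted values are capped at 1, never smaller than the raw value, and
#' monotone in rank.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-genotype logrank screen of a lifespan table
#'
#' For every genotype with events in both arms, tests control vs heat
#' survival with [logrank_test()] and adjusts the p-values across genotypes
#' with [fdr_adjust()].
#'
#' @param surv A [survival_table()].
#' @param alpha FDR threshold used for the `significant` flag; default 0.05.
#' @return A data frame of class `logrank_screen` with columns `genotype`,
#'   `statistic`, `p`, `p_fdr`, `significant`.
#' @export
logrank_screen <- function(surv, alpha = 0.05) {
  genotypes <- unique(surv$genotype)
  rows <- list()
  for (g in genotypes) {
    sel_c <- surv$genotype == g & surv$treatment == "control"
    sel_h <- surv$genotype == g & surv$treatment == "heat"
    if (!any(sel_c) || !any(sel_h)) next
    lr <- logrank_test(surv$day[sel_c], surv$status[sel_c],
                       surv$day[sel_h], surv$status[sel_h])
    rows[[g]] <- data.frame(genotype = g, statistic = lr$statistic, p = lr$p,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no genotype has both arms")
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p)
  out$significant <- out$p_fdr < alpha
  rownames(out) <- NULL
  class(out) <- c("logrank_screen", "data.frame")
  out
}

#' Count genotypes significantly affected by the stress
#'
#' @param results A `logrank_screen` data frame (with `p_fdr`).
#' @param alpha FDR threshold; default 0.05.
#' @return A list with `n_significant` (FDR below `alpha`) and `n_not`.
#' @export
count_significant <- function(results, alpha = 0.05) {
  if (is.null(results) || nrow(results) == 0L)
    return(list(n_significant = 0L, n_not = 0L))
  if (!"p_fdr" %in% names(results)) stop("'p_fdr' column is required")
  list(n_significant = sum(results$p_fdr < alpha),
       n_not = sum(results$p_fdr >= alpha))
}

#' Full lifespan reanalysis from a cumulative-death file
#'
#' Convenience wrapper reproducing the lifespan screen from a file in the
#' cumulative-death format: parse, per-genotype logrank (control vs heat),
#' BH-FDR adjustment, and counts of affected / unaffected lines, alongside
#' per-genotype thermotolerance ratios.
#'
#' @param path Path to a cumulative-death lifespan table
#'   (see [read_survival_cumulative()]).
#' @param alpha FDR threshold; default 0.05.
#' @param direction Ratio orientation for [thermotolerance()].
#' @return A list with `survival` (the parsed table), `logrank` (the
#'   screen), `thermotolerance`, `n_significant` and `n_not`.
#' @export
reanalyze_lifespan <- function(path, alpha = 0.05,
                               direction = "heat_over_control") {
  surv <- read_survival_cumulative(path)
  screen <- logrank_screen(surv, alpha = alpha)
  counts <- count_significant(screen, alpha = alpha)
  thermo <- thermotolerance(surv, direction = direction)
  list(survival = surv, logrank = screen, thermotolerance = thermo,
       n_significant = counts$n_significant, n_not = counts$n_not)
}
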
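#' Configuration of the synthetic study generator
#'
#' Returns the parameter list controlling [simulate_expression()] and
#' [simulate_survival()]. The generator emulates the statistical structure
#' the axis analysis assumes: a bimodal distribution of mean log2
#' intensities (an unexpressed low mode and an expressed high mode), a
#' smooth developmental trend shared by all samples, a saturating
#' stress-dose trend with a positively skewed gene-loading distribution
#' (more genes up- than down-regulated under stress), a dominant per-array
#' technical intensity factor (so that, as in real microarray series, the
#' biological trend lands on the second principal component), genotype
#' baseline offsets, and genotype-specific recovery rates that slow with
#' accumulated stress dose. Lifespan ratios are planted to increase with
#' the recovery rate, so slow transcriptional recoverers are also the least
#' thermotolerant.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `sim_config`.
#' @section Parameters:
#' \describe{
#'   \item{n_genes, n_genotypes}{2000 genes, 40 inbred-line genotypes (plus
#'     the reference genotype N2).}
#'   \item{low_expression_fraction}{0.3 of genes in the unexpressed mode.}
#'   \item{mean_low, sd_low, mean_high, sd_high}{Baseline mean log2
#'     intensity mixture: Normal(3, 0.5) and Normal(8, 1.5).}
#'   \item{dev_sd}{SD of per-gene developmental loadings, 0.4 log2 units
#'     per SD of developmental time.}
#'   \item{stress_mean, stress_sd}{Per-gene stress loadings
#'     Normal(0.25, 1.25) log2 units per unit dose; the positive mean
#'     plants the asymmetric loading distribution.}
#'   \item{geno_sd}{SD of per-gene genotype-baseline loadings, 0.3.}
#'   \item{array_effect_sd, array_loading_mean, array_loading_sd}{Technical
#'     per-array intensity factor: sample effect Normal(0, 1) with gene
#'     loadings Normal(1, 0.3).}
#'   \item{noise_sd}{Residual noise, 0.25 log2 units.}
#'   \item{dev_rate_heat}{Rate of developmental progression during heat
#'     exposure relative to 20 C, default 0.2 (development is largely
#'     arrested at the stress temperature; `t_dev` metadata stay on the
#'     wall clock, the generator converts internally).}
#'   \item{u_sat, tau}{Dose saturation level 1 and time constant 2 h.}
#'   \item{rho0_meanlog, rho0_sdlog}{Genotype recovery rates
#'     LogNormal(log 0.5, 0.4) per hour.}
#'   \item{lambda}{Dose-dependent recovery slowing, 1.5 per unit dose.}
#'   \item{sense_coupling}{Exponent linking genotype stress sensitivity to
#'     the recovery rate, `q_k = (rho0_k / rho0_ref)^(-coupling)`; default
#'     1 (0 disables genotype-dependent dosing).}
#'   \item{n_ref_replicates}{Replicate arrays of the reference genotype per
#'     panel condition, 5.}
#'   \item{lifespan_mean, lifespan_sd, n_worms}{Control lifespans
#'     Normal(17, 2.5) days, 31 animals per arm.}
#'   \item{ratio_base, ratio_span, ratio_noise}{Lifespan-ratio map
#'     `r = 0.45 + 0.5 * pnorm(standardized log rho0) + Normal(0, 0.05)`,
#'     clipped to (0, 1.1].}
#'   \item{min_day}{Lifespan floor, 2 days.}
#'   \item{seed}{RNG seed, 42.}
#' }
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 2000L, n_genotypes = 40L,
    low_expression_fraction = 0.3,
    mean_low = 3, sd_low = 0.5, mean_high = 8, sd_high = 1.5,
    dev_sd = 0.4, stress_mean = 0.25, stress_sd = 1.25, geno_sd = 0.3,
    array_effect_sd = 1.0, array_loading_mean = 1, array_loading_sd = 0.3,
    noise_sd = 0.25,
    dev_rate_heat = 0.2,
    u_sat = 1, tau = 2,
    rho0_meanlog = log(0.5), rho0_sdlog = 0.4,
    lambda = 1.5, sense_coupling = 1,
    n_ref_replicates = 5L,
    lifespan_mean = 17, lifespan_sd = 2.5, n_worms = 31L,
    ratio_base = 0.45, ratio_span = 0.5, ratio_noise = 0.05, min_day = 2,
    seed = 42L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown sim_config parameter(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, overrides)
  scales <- c("sd_low", "sd_high", "dev_sd", "stress_sd", "geno_sd",
              "noise_sd", "u_sat", "tau", "rho0_sdlog", "lifespan_sd")
  if (any(unlist(cfg[scales]) <= 0))
    stop("all scale parameters must be > 0")
  if (cfg$low_expression_fraction <= 0 || cfg$low_expression_fraction >= 1)
    stop("low_expression_fraction must lie in (0, 1)")
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Effective stress dose during exposure and recovery
#'
#' The latent physiological stress load accumulates towards saturation
#' during heat exposure, `u(t) = q * u_sat * (1 - exp(-t_heat / tau))`, and
#' decays exponentially during recovery at a genotype- and dose-dependent
#' rate: `u = u_end * exp(-rho_eff * t_rec)` with
#' `rho_eff = rho0 * exp(-lambda * u_end)`, so longer exposures recover
#' more slowly. The genotype sensitivity
#' `q = (rho0 / rho0_ref)^(-sense_coupling)` makes slowly recovering
#' genotypes accumulate more dose from the same exposure (set
#' `sense_coupling = 0` for genotype-independent dosing); at the reference
#' recovery rate `q = 1`.
#'
#' @param t_heat,t_rec Hours of heat exposure and of recovery (vectors
#'   recycle).
#' @param rho0 Genotype base recovery rate(s), per hour.
#' @param cfg A [sim_config()].
#' @return Numeric vector of effective doses, `>= 0`.
#' @export
simulate_dose <- function(t_heat, t_rec, rho0, cfg = sim_config()) {
  stopifnot(all(t_heat >= 0), all(t_rec >= 0), all(rho0 > 0))
  q <- (rho0 / exp(cfg$rho0_meanlog))^(-cfg$sense_coupling)
  u_end <- q * cfg$u_sat * (1 - exp(-t_heat / cfg$tau))
  rho_eff <- rho0 * exp(-cfg$lambda * u_end)
  ifelse(t_rec > 0, u_end * exp(-rho_eff * t_rec), u_end)
}

# sampling design: reference-genotype time series (development, heat,
# recovery after several exposure durations) plus a genotype panel with
# control / heat / recovery arrays per line and replicate reference arrays
build_sample_sheet <- function(cfg) {
  ref <- "N2"
  sheets <- list()
  # development series: hourly, alternating train/test
  t_dev <- 44:61
  sheets$dev <- data.frame(
    genotype = ref, treatment = "control", t_dev = t_dev, t_heat = 0,
    t_rec = 0, split = rep(c("train", "test"), length.out = length(t_dev)),
    series = "dev_series", stringsAsFactors = FALSE)
  # heat series (exposure starts at 46 h of development)
  heat_train <- c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 6)
  heat_test <- c(0.5, 1, 2, 3, 4, 6)
  sheets$heat <- data.frame(
    genotype = ref, treatment = "heat",
    t_dev = 46 + c(heat_train, heat_test),
    t_heat = c(heat_train, heat_test), t_rec = 0,
    split = rep(c("train", "test"), c(length(heat_train), length(heat_test))),
    series = "heat_series", stringsAsFactors = FALSE)
  # recovery series after 2, 3, 4, 6 h of stress
  rec <- rbind(
    data.frame(t_heat = 2, t_rec = c(0.5, 1, 1.5, 2, 4, 6)),
    data.frame(t_heat = 3, t_rec = 1:4),
    data.frame(t_heat = 4, t_rec = 1:4),
    data.frame(t_heat = 6, t_rec = 1:4))
  sheets$rec <- data.frame(
    genotype = ref, treatment = "recovery", t_dev = 46 + rec$t_heat + rec$t_rec,
    t_heat = rec$t_heat, t_rec = rec$t_rec, split = "test",
    series = "recovery_series", stringsAsFactors = FALSE)
  # genotype panel: one array per line and condition (2 h stress, 2 h recovery)
  lines <- sprintf("RIL%02d", seq_len(cfg$n_genotypes))
  panel <- expand.grid(genotype = lines,
                       treatment = c("control", "heat", "recovery"),
                       stringsAsFactors = FALSE)
  panel$t_heat <- ifelse(panel$treatment == "control", 0, 2)
  panel$t_rec <- ifelse(panel$treatment == "recovery", 2, 0)
  panel$t_dev <- 48 + panel$t_rec
  panel$split <- ifelse(panel$treatment == "recovery", "test", "train")
  panel$series <- "panel"
  sheets$panel <- panel[, names(sheets$dev)]
  # replicate reference arrays in the panel conditions
  if (cfg$n_ref_replicates > 0L) {
    reps <- expand.grid(rep = seq_len(cfg$n_ref_replicates),
                        treatment = c("control", "heat", "recovery"),
                        stringsAsFactors = FALSE)
    sheets$refrep <- data.frame(
      genotype = ref, treatment = reps$treatment,
      t_dev = 48 + ifelse(reps$treatment == "recovery", 2, 0),
      t_heat = ifelse(reps$treatment == "control", 0, 2),
      t_rec = ifelse(reps$treatment == "recovery", 2, 0),
      split = "test", series = "ref_replicates", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, sheets)
  out$sample_id <- sprintf("s%03d_%s", seq_len(nrow(out)),
                           substr(out$treatment, 1, 3))
  rownames(out) <- NULL
  out[, c("sample_id", "genotype", "treatment", "t_dev", "t_heat", "t_rec",
          "split", "series")]
}

#' Simulate a gene-expression study with planted structure
#'
#' Generates log2 expression for the full sampling design (reference-strain
#' development, heat and recovery time series plus a genotype panel; see
#' [sim_config()]) under the additive model
#' `x = m_g + a_g * dev(t) + b_g * u_s + c_g * z_k + w_g * e_s + noise`,
#' where `dev(t)` is standardized developmental time, `u_s` the effective
#' stress dose of the sample, `z_k` the genotype's latent baseline trait,
#' and `e_s` a per-array technical intensity factor. Deterministic given
#' the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A list with `dataset` (an [expression_dataset()]) and `truth`, a
#'   list with `samples` (per-sample planted dose `u`), `genotypes`
#'   (per-genotype `rho0`, sensitivity `q`, latent trait `z`) and `genes`
#'   (per-gene planted loadings).
#' @export
simulate_expression <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  samples <- build_sample_sheet(cfg)
  lines <- setdiff(unique(samples$genotype), "N2")
  geno <- data.frame(
    genotype = c("N2", lines),
    rho0 = c(exp(cfg$rho0_meanlog),
             stats::rlnorm(length(lines), cfg$rho0_meanlog, cfg$rho0_sdlog)),
    z = c(0, stats::rnorm(length(lines))),
    stringsAsFactors = FALSE)
  geno$q <- (geno$rho0 / exp(cfg$rho0_meanlog))^(-cfg$sense_coupling)

  gi <- match(samples$genotype, geno$genotype)
  u <- simulate_dose(samples$t_heat, samples$t_rec, geno$rho0[gi], cfg)
  # developmental age: hours at the stress temperature count at a reduced
  # rate (near-arrest), so t_dev is wall clock but the planted trend is not
  age <- samples$t_dev - (1 - cfg$dev_rate_heat) * samples$t_heat
  dev_scaled <- as.numeric(scale(age))
  z_s <- geno$z[gi]
  e_array <- stats::rnorm(nrow(samples), 0, cfg$array_effect_sd)

  ng <- cfg$n_genes
  low <- stats::runif(ng) < cfg$low_expression_fraction
  m <- ifelse(low, stats::rnorm(ng, cfg$mean_low, cfg$sd_low),
              stats::rnorm(ng, cfg$mean_high, cfg$sd_high))
  a <- stats::rnorm(ng, 0, cfg$dev_sd)
  b <- stats::rnorm(ng, cfg$stress_mean, cfg$stress_sd)
  c_g <- stats::rnorm(ng, 0, cfg$geno_sd)
  w <- stats::rnorm(ng, cfg$array_loading_mean, cfg$array_loading_sd)

  X <- m +
    a %o% dev_scaled +
    b %o% u +
    c_g %o% z_s +
    w %o% e_array +
    matrix(stats::rnorm(ng * nrow(samples), 0, cfg$noise_sd), ng)
  dimnames(X) <- list(sprintf("g%04d", seq_len(ng)), samples$sample_id)

  ds <- expression_dataset(X, samples[, required_sample_columns()])
  truth <- list(
    samples = data.frame(sample_id = samples$sample_id, u = u,
                         series = samples$series, stringsAsFactors = FALSE),
    genotypes = geno,
    genes = data.frame(gene_id = rownames(X), m = m, a = a, b = b, c = c_g,
                       w = w, low = low, stringsAsFactors = FALSE))
  list(dataset = ds, truth = truth)
}

#' Simulate lifespan assays linked to the planted recovery rates
#'
#' For every genotype of the planted truth, draws a control arm of
#' `n_worms` lifespans from Normal(`lifespan_mean`, `lifespan_sd`), maps
#' the genotype's recovery rate to a true lifespan ratio
#' `r_k = ratio_base + ratio_span * pnorm(standardized log rho0) + noise`
#' (fast recoverers are barely affected, `r` near 0.95), and draws the
#' heat arm from Normal(`lifespan_mean * r_k`, `lifespan_sd`). Lifespans
#' are rounded to integer days and floored at `min_day`. Deterministic
#' given the config seed (the generator uses `seed + 1` so that expression
#' and survival draws are independent).
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list from [simulate_expression()].
#' @return A list with `table` (a [survival_table()]) and `truth` (the
#'   input truth with a per-genotype `r_true` column added).
#' @export
simulate_survival <- function(cfg, truth) {
  set.seed(cfg$seed + 1L)
  geno <- truth$genotypes
  eta <- (log(geno$rho0) - cfg$rho0_meanlog) / cfg$rho0_sdlog
  r <- cfg$ratio_base + cfg$ratio_span * stats::pnorm(eta) +
    stats::rnorm(nrow(geno), 0, cfg$ratio_noise)
  r <- pmin(pmax(r, 0.05), 1.1)
  draw <- function(mu) pmax(round(stats::rnorm(cfg$n_worms, mu, cfg$lifespan_sd)),
                            cfg$min_day)
  rows <- lapply(seq_len(nrow(geno)), function(i) {
    rbind(data.frame(genotype = geno$genotype[i], treatment = "control",
                     day = draw(cfg$lifespan_mean), stringsAsFactors = FALSE),
          data.frame(genotype = geno$genotype[i], treatment = "heat",
                     day = draw(cfg$lifespan_mean * r[i]),
                     stringsAsFactors = FALSE))
  })
  df <- do.call(rbind, rows)
  geno$r_true <- r
  truth$genotypes <- geno
  list(table = survival_table(df$genotype, df$treatment, df$day),
       truth = truth)
}

#' Simulate a complete linked study
#'
#' Convenience wrapper generating the expression compendium and the matched
#' lifespan assay in one call.
#'
#' @param cfg A [sim_config()].
#' @return A list with `expression` (an [expression_dataset()]), `survival`
#'   (a [survival_table()]) and `truth` (planted parameters: per-sample
#'   dose, per-genotype recovery rate, latent trait, sensitivity and true
#'   lifespan ratio, per-gene loadings).
#' @export
simulate_study <- function(cfg = sim_config()) {
  ex <- simulate_expression(cfg)
  sv <- simulate_survival(cfg, ex$truth)
  list(expression = ex$dataset, survival = sv$table, truth = sv$truth)
}
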
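#' Read and validate a pipeline run configuration
#'
#' Configurations are plain lists (or YAML files) with the blocks below;
#' every field has a default, so `run_config()` alone is a valid demo
#' configuration that simulates its own data.
#'
#' \describe{
#'   \item{seed}{Integer; flows to every random stage.}
#'   \item{input}{Optional paths `expression`, `metadata`, `survival`; when
#'     absent the synthetic generator supplies the data.}
#'   \item{sim}{Named overrides for [sim_config()] (used only when no input
#'     paths are given).}
#'   \item{filter}{`threshold` (log2 mean-intensity cutoff, default 4.5).}
#'   \item{axes}{`component_mode` (`"fixed_second"` or
#'     `"max_association"`), `k`, `ref_genotype` (default `"N2"`).}
#'   \item{survival}{`alpha` (FDR threshold, 0.05) and `ratio_direction`.}
#'   \item{subset_sd}{`n_reps` (default 5000).}
#'   \item{enrichment}{Optional `gene_sets` (GMT path) and `fraction`
#'     (top-contributor fraction, default 0.05).}
#'   \item{out_dir}{Optional directory; when set, tables, a summary and a
#'     manifest are written there.}
#' }
#'
#' @param config A named list of overrides, or a path to a YAML file.
#' @return Validated configuration list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(
    seed = 42L,
    input = list(expression = NULL, metadata = NULL, survival = NULL),
    sim = list(),
    filter = list(threshold = 4.5),
    axes = list(component_mode = "fixed_second", k = 5L, ref_genotype = "N2"),
    survival = list(alpha = 0.05, ratio_direction = "heat_over_control"),
    subset_sd = list(n_reps = 5000L),
    enrichment = list(gene_sets = NULL, fraction = 0.05),
    out_dir = NULL)
  cfg <- utils::modifyList(defaults, config)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop("config$seed must be a single integer")
  if (!is.numeric(cfg$filter$threshold))
    stop("config$filter$threshold must be numeric")
  if (!cfg$axes$component_mode %in% c("fixed_second", "max_association"))
    stop("config$axes$component_mode must be 'fixed_second' or 'max_association'")
  if (!is.numeric(cfg$survival$alpha) || cfg$survival$alpha <= 0 ||
      cfg$survival$alpha >= 1)
    stop("config$survival$alpha must lie in (0, 1)")
  if (!cfg$survival$ratio_direction %in% c("heat_over_control",
                                           "control_over_heat"))
    stop("config$survival$ratio_direction is invalid")
  has_input <- !is.null(cfg$input$expression)
  if (has_input && (is.null(cfg$input$metadata) || is.null(cfg$input$survival)))
    stop("config$input must name expression, metadata and survival paths together")
  if (has_input) {
    for (p in unlist(cfg$input))
      if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the full resilience analysis pipeline
#'
#' Orchestrates every stage: data acquisition (synthetic generation or
#' loading from disk), low-expression filtering, derivation of the
#' developmental / heat-stress axis pair from the reference-genotype time
#' series, projection of all samples, derivation of the genotype axis pair
#' from the inbred-line panel, genotype resilience scoring, the subset-SD
#' variability analysis, the lifespan screen (thermotolerance ratios,
#' per-genotype logrank with FDR control), the resilience-thermotolerance
#' rank correlation, and optional top-contributor enrichment. When
#' `out_dir` is set, result tables plus a JSON manifest (inputs, checksums,
#' seed, package version) are written there.
#'
#' @param config A [run_config()], a named list of overrides, or a YAML
#'   path.
#' @return Invisibly, a list with elements `dataset`, `axes` (`D`, `H`,
#'   `GD`, `GH`), `projections` (`H`, `D`, `GH_recovery`, `GH_panel`),
#'   `resilience`, `subset_sd`, `survival` (screen, counts,
#'   thermotolerance), `correlation`, `enrichment` (or `NULL`) and `truth`
#'   (planted parameters, synthetic mode only).
#' @examples
#' \donttest{
#' res <- run_pipeline(list(sim = list(n_genes = 300, n_genotypes = 12)))
#' res$correlation
#' }
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)

  # -- data -----------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$input$expression)) {
    ds <- read_expression(cfg$input$expression, cfg$input$metadata)
    surv <- read_survival_cumulative(cfg$input$survival)
  } else {
    sim_cfg <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                                     cfg$sim))
    study <- simulate_study(sim_cfg)
    ds <- study$expression
    surv <- study$survival
    truth <- study$truth
  }

  # -- filtering ------------------------------------------------------------
  ds <- filter_low_expression(ds, cfg$filter$threshold)
  ref <- cfg$axes$ref_genotype
  axis_cfg <- list(component_mode = cfg$axes$component_mode, k = cfg$axes$k)

  # -- reference-strain axes (D, H) ----------------------------------------
  ctrl_train <- select_samples(ds, genotype == ref, treatment == "control",
                               split == "train")
  heat_train <- select_samples(ds, genotype == ref, treatment == "heat",
                               split == "train")
  dh <- derive_axis_pair(ctrl_train, heat_train,
                         utils::modifyList(axis_cfg, list(names = c("D", "H"))))
  proj_h <- project(ds, dh$H)
  proj_d <- project(ds, dh$D)

  # -- genotype axes (GD, GH) ----------------------------------------------
  panel_ctrl <- select_samples(ds, genotype != ref, treatment == "control",
                               split == "train")
  panel_heat <- select_samples(ds, genotype != ref, treatment == "heat",
                               split == "train")
  orientation <- select_samples(ds, genotype != ref, treatment != "recovery")
  gdgh <- derive_axis_pair(
    panel_ctrl, panel_heat,
    utils::modifyList(axis_cfg, list(
      control_covariate = "treatment", stress_covariate = "treatment",
      orientation_data = orientation, names = c("GD", "GH"))))

  panel_rec <- select_samples(ds, genotype != ref, treatment == "recovery")
  proj_gh_rec <- project(panel_rec, gdgh$GH)
  panel_all <- select_samples(ds, genotype != ref)
  proj_gh_panel <- project(panel_all, gdgh$GH)
  resilience <- score_resilience(rbind(proj_gh_rec,
                                       proj_gh_panel[proj_gh_panel$treatment !=
                                                       "recovery", ]))

  # -- subset-SD variability analysis on H ----------------------------------
  subset_reports <- list()
  panel_cond <- list(control = quote(t_dev == 48 & t_heat == 0),
                     heat = quote(t_heat == 2 & t_rec == 0),
                     recovery = quote(t_heat == 2 & t_rec == 2))
  for (treat in c("control", "heat", "recovery")) {
    is_cond <- eval(panel_cond[[treat]], proj_h)
    ref_scores <- proj_h$score[proj_h$genotype == ref &
                                 proj_h$treatment == treat &
                                 proj_h$split == "test" & is_cond]
    pool <- proj_h$score[proj_h$genotype != ref & proj_h$treatment == treat]
    if (length(ref_scores) >= 2L && length(pool) >= length(ref_scores)) {
      subset_reports[[treat]] <- subset_sd_distribution(
        pool, n_subset = length(ref_scores), n_reps = cfg$subset_sd$n_reps,
        seed = cfg$seed + 100L, reference_sd = stats::sd(ref_scores),
        treatment = NULL)
      subset_reports[[treat]]$treatment <- treat
    }
  }

  # -- lifespan screen ------------------------------------------------------
  screen <- logrank_screen(surv, alpha = cfg$survival$alpha)
  counts <- count_significant(screen, alpha = cfg$survival$alpha)
  thermo <- thermotolerance(surv, direction = cfg$survival$ratio_direction)

  # -- resilience vs thermotolerance ----------------------------------------
  merged <- merge(resilience, thermo, by = "genotype")
  merged <- merged[is.finite(merged$gh_recovery), , drop = FALSE]
  correlation <- if (nrow(merged) >= 3L)
    spearman_cor(merged$gh_recovery, merged$ratio) else NULL

  # -- enrichment (optional) ------------------------------------------------
  enrichment <- NULL
  if (!is.null(cfg$enrichment$gene_sets)) {
    sets <- read_gene_sets(cfg$enrichment$gene_sets)
    top <- top_contributors(dh$H, fraction = cfg$enrichment$fraction)
    enrichment <- hypergeometric_enrichment(top$gene_id, sets, gene_ids(ds))
  }

  results <- list(dataset = ds,
                  axes = list(D = dh$D, H = dh$H, GD = gdgh$GD, GH = gdgh$GH),
                  axes_provenance = list(DH = attr(dh, "provenance"),
                                         GDGH = attr(gdgh, "provenance")),
                  projections = list(H = proj_h, D = proj_d,
                                     GH_recovery = proj_gh_rec,
                                     GH_panel = proj_gh_panel),
                  resilience = resilience,
                  subset_sd = subset_reports,
                  survival = list(screen = screen, counts = counts,
                                  thermotolerance = thermo),
                  correlation = correlation,
                  enrichment = enrichment,
                  truth = truth,
                  config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(results, cfg)
  invisible(results)
}

write_pipeline_outputs <- function(results, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(cfg$out_dir, ...)
  wt <- function(df, name) utils::write.table(df, p(name), sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  for (nm in names(results$projections))
    wt(results$projections[[nm]], paste0("projection_", nm, ".tsv"))
  wt(results$resilience, "resilience_scores.tsv")
  wt(results$survival$screen, "logrank_screen.tsv")
  wt(results$survival$thermotolerance, "thermotolerance.tsv")
  if (!is.null(results$enrichment)) wt(results$enrichment, "enrichment.tsv")
  for (nm in names(results$axes)) {
    ax <- results$axes[[nm]]
    wt(data.frame(gene_id = ax$gene_ids, loading = unname(ax$loadings)),
       paste0("axis_", nm, ".tsv"))
  }
  summary <- list(
    n_genes = nrow(results$dataset$values),
    n_samples = ncol(results$dataset$values),
    n_significant = results$survival$counts$n_significant,
    n_not_significant = results$survival$counts$n_not,
    resilience_thermotolerance_rho =
      if (is.null(results$correlation)) NA else results$correlation$rho,
    resilience_thermotolerance_p =
      if (is.null(results$correlation)) NA else results$correlation$p)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  inputs <- Filter(Negate(is.null), cfg$input)
  manifest <- list(
    package_version = as.character(utils::packageVersion("resilax")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = unclass(cfg)[setdiff(names(cfg), "out_dir")],
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(unlist(inputs))) else list(),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(results)
}
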
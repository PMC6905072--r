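std_meta <- function(n, treatment = "control",
                     t_dev = seq(44, length.out = n),
                     t_heat = if (treatment == "control") 0 else seq_len(n),
                     t_rec = 0) {
  data.frame(sample_id = sprintf("s%02d", seq_len(n)), genotype = "N2",
             treatment = treatment, t_dev = t_dev, t_heat = t_heat,
             t_rec = t_rec, split = "train", stringsAsFactors = FALSE)
}

test_that("PCA recovers a planted rank-1 direction and is orthonormal", {
  set.seed(11)
  n_genes <- 120; n_samples <- 12
  v <- rnorm(n_genes); v <- v / sqrt(sum(v^2))
  scores <- rnorm(n_samples, sd = 3)
  X <- v %o% scores + matrix(rnorm(n_genes * n_samples, sd = 0.02), n_genes)
  dimnames(X) <- list(sprintf("g%03d", 1:n_genes), sprintf("s%02d", 1:n_samples))
  ds <- expression_dataset(X, std_meta(n_samples))
  st <- fit_standardizer(ds)
  pa <- fit_principal_axes(apply_standardizer(ds, st), st, k = 5)
  expect_gt(abs(sum(pa$loadings[, 1] * v / st$sd) /
                  sqrt(sum((v / st$sd)^2))), 0.99)
  expect_equal(crossprod(pa$loadings), diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(pa$variance_explained) <= 1e-12))
  expect_lte(sum(pa$variance_explained), 1 + 1e-12)
  expect_error(fit_principal_axes(apply_standardizer(ds, st), st, k = 50),
               "exceeds the rank")
})

test_that("component selection honours both modes and warns on disagreement", {
  # default generator: technical factor on PC1, developmental trend on PC2
  sim <- simulate_expression(small_config())
  ds <- suppressMessages(filter_low_expression(sim$dataset))
  ctrl <- select_samples(ds, genotype == "N2", treatment == "control",
                         split == "train")
  st <- fit_standardizer(ctrl)
  pa <- fit_principal_axes(apply_standardizer(ctrl, st), st, k = 4)
  fixed <- select_component(pa, mode = "fixed_second")
  assoc <- select_component(pa, covariate = ctrl$samples$t_dev,
                            mode = "max_association")
  expect_identical(fixed$component_index, 2L)
  expect_identical(assoc$component_index, 2L)
  expect_equal(abs(sum(fixed$loadings * assoc$loadings)), 1, tolerance = 1e-9)

  # without the technical factor the trend dominates and lands on PC1
  sim2 <- simulate_expression(small_config(array_effect_sd = 1e-4))
  ds2 <- suppressMessages(filter_low_expression(sim2$dataset))
  ctrl2 <- select_samples(ds2, genotype == "N2", treatment == "control",
                          split == "train")
  st2 <- fit_standardizer(ctrl2)
  pa2 <- fit_principal_axes(apply_standardizer(ctrl2, st2), st2, k = 4)
  expect_warning(assoc2 <- select_component(pa2, covariate = ctrl2$samples$t_dev,
                                            mode = "max_association"),
                 "PC1, not PC2")
  expect_identical(assoc2$component_index, 1L)
  expect_identical(select_component(pa2, mode = "fixed_second")$component_index,
                   2L)
  expect_error(select_component(pa2, covariate = rep(1, 9),
                                mode = "max_association"), "constant")
})

test_that("orthogonalization matches hand-computed cases", {
  g <- c("g1", "g2", "g3")
  d <- manual_axis(setNames(c(1, 0, 0), g), name = "D")
  # already orthogonal: unchanged
  h1 <- manual_axis(setNames(c(0, 0, 1), g))
  o1 <- orthogonalize(h1, d)
  expect_equal(unname(o1$loadings), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(o1$confound_overlap, 0, tolerance = 1e-12)
  # 45-degree case: residual is the second basis vector, overlap 1/sqrt(2)
  h2 <- manual_axis(setNames(c(1, 1, 0) / sqrt(2), g))
  o2 <- orthogonalize(h2, d)
  expect_equal(unname(o2$loadings), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(o2$confound_overlap, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(sum(o2$loadings * d$loadings), 0, tolerance = 1e-12)
  # parallel axes are degenerate
  expect_error(orthogonalize(d, d), "degenerate")
})

test_that("orientation flips against the covariate and is idempotent", {
  g <- c("g1", "g2")
  ax <- manual_axis(setNames(c(1, 0), g), name = "H")
  X <- rbind(g1 = c(4, 3, 2, 1), g2 = c(0, 0, 0, 0.5))
  colnames(X) <- sprintf("s%02d", 1:4)
  ds <- expression_dataset(X, std_meta(4, treatment = "heat",
                                       t_dev = 46 + 1:4, t_heat = 1:4))
  flipped <- orient_axis(ax, ds, "t_heat")
  expect_equal(unname(flipped$loadings), c(-1, 0))
  # scores now increase with t_heat; a second application changes nothing
  again <- orient_axis(flipped, ds, "t_heat")
  expect_identical(again$loadings, flipped$loadings)
  # weak association leaves the sign alone with a warning
  noise_ds <- expression_dataset(
    rbind(g1 = c(0.1, -0.2, -0.15, 0.25), g2 = c(1, 2, 3, 4)) |>
      `colnames<-`(sprintf("s%02d", 1:4)),
    std_meta(4, treatment = "heat", t_dev = 46 + 1:4, t_heat = c(1, 2, 1, 2)))
  expect_warning(orient_axis(ax, noise_ds, "t_heat"), "no clear association")
})

test_that("projection centers the training mean at zero and is linear", {
  run <- default_run()
  H <- run$axes$H
  st <- H$standardizer
  meta1 <- data.frame(sample_id = "m", genotype = "N2", treatment = "control",
                      t_dev = 48, t_heat = 0, t_rec = 0, split = "test")
  mean_ds <- expression_dataset(
    matrix(st$mean, ncol = 1, dimnames = list(st$gene_ids, "m")), meta1)
  expect_equal(project(mean_ds, H)$score, 0, tolerance = 1e-9)

  # convex combinations of raw profiles project to the same combination of scores
  ds <- run$dataset
  x1 <- ds$values[, 1]; x2 <- ds$values[, 2]
  alpha <- 0.3
  mix <- alpha * x1 + (1 - alpha) * x2
  meta3 <- data.frame(sample_id = c("a", "b", "mix"), genotype = "N2",
                      treatment = "control", t_dev = 48, t_heat = 0,
                      t_rec = 0, split = "test")
  trio <- expression_dataset(cbind(a = x1, b = x2, mix = mix), meta3)
  sc <- project(trio, H)$score
  expect_equal(sc[3], alpha * sc[1] + (1 - alpha) * sc[2], tolerance = 1e-9)
})

test_that("projection is invariant to gene reordering of the input", {
  run <- default_run()
  ds <- run$dataset
  perm <- sample(nrow(ds$values))
  expect_equal(project(ds[perm, ], run$axes$H)$score,
               project(ds, run$axes$H)$score, tolerance = 1e-9)
})

test_that("derived axis pairs are unit-norm, orthogonal and reproducible", {
  run <- default_run()
  for (nm in c("D", "H", "GD", "GH"))
    expect_equal(sum(run$axes[[nm]]$loadings^2), 1, tolerance = 1e-9)
  expect_equal(sum(run$axes$H$loadings * run$axes$D$loadings[run$axes$H$gene_ids]),
               0, tolerance = 1e-9)
  expect_equal(sum(run$axes$GH$loadings * run$axes$GD$loadings[run$axes$GH$gene_ids]),
               0, tolerance = 1e-9)

  # rerunning the full derivation on the same inputs gives identical axes
  ds <- run$dataset
  ctrl <- select_samples(ds, genotype == "N2", treatment == "control",
                         split == "train")
  heat <- select_samples(ds, genotype == "N2", treatment == "heat",
                         split == "train")
  p1 <- derive_axis_pair(ctrl, heat)
  p2 <- derive_axis_pair(ctrl, heat)
  expect_identical(p1$D$loadings, p2$D$loadings)
  expect_identical(p1$H$loadings, p2$H$loadings)
})

test_that("genotype heat-stress axis separates heat from control per genotype", {
  run <- default_run()
  proj <- run$projections$GH_panel
  by_geno <- split(proj, proj$genotype)
  diffs <- vapply(by_geno, function(d) {
    mean(d$score[d$treatment == "heat"]) -
      mean(d$score[d$treatment == "control"])
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.95)
  expect_gt(mean(diffs), 0)
})
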
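test_that("effective dose saturates with exposure and decays in recovery", {
  cfg <- sim_config()
  rho_ref <- exp(cfg$rho0_meanlog)
  expect_equal(simulate_dose(0, 0, rho_ref, cfg), 0)
  expect_equal(simulate_dose(1e6, 0, rho_ref, cfg), cfg$u_sat,
               tolerance = 1e-9)
  # closed form during exposure
  expect_equal(simulate_dose(2, 0, rho_ref, cfg), 1 - exp(-1),
               tolerance = 1e-12)
  # dose-dependent slowing: residual dose after 4 h of recovery is larger
  # following 6 h of stress than following 2 h
  expect_lt(simulate_dose(2, 4, rho_ref, cfg),
            simulate_dose(6, 4, rho_ref, cfg))
  # monotone decay over recovery time
  u <- simulate_dose(rep(2, 4), c(0, 1, 2, 4), rho_ref, cfg)
  expect_true(all(diff(u) < 0))
  # slow recoverers accumulate more dose through the sensitivity coupling
  expect_gt(simulate_dose(2, 0, rho_ref / 2, cfg),
            simulate_dose(2, 0, rho_ref * 2, cfg))
  # coupling off reproduces the genotype-independent dose curve
  cfg0 <- sim_config(sense_coupling = 0)
  expect_equal(simulate_dose(2, 0, rho_ref / 2, cfg0), 1 - exp(-1),
               tolerance = 1e-12)
})

test_that("expression generator is deterministic and structured as planted", {
  cfg <- small_config()
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$dataset$values, s2$dataset$values)
  expect_identical(s1$truth$genotypes, s2$truth$genotypes)

  ds <- s1$dataset
  validate_expression_dataset(ds)
  expect_true(all(s1$truth$samples$u >= 0))
  # gene means are bimodal with roughly the configured low fraction
  means <- rowMeans(ds$values)
  expect_lt(abs(mean(means < 5.5) - cfg$low_expression_fraction), 0.07)
  # the planted low-mode genes really sit in the low intensity mode
  expect_gt(mean(means[s1$truth$genes$low] < 4.5), 0.95)
  expect_gt(mean(means[!s1$truth$genes$low] > 4.5), 0.9)
})

test_that("without stress loadings the derived axis carries no dose signal", {
  cfg <- sim_config(stress_mean = 0, stress_sd = 1e-6)
  sim <- simulate_expression(cfg)
  ds <- suppressMessages(filter_low_expression(sim$dataset))
  ctrl <- select_samples(ds, genotype == "N2", treatment == "control",
                         split == "train")
  heat <- select_samples(ds, genotype == "N2", treatment == "heat",
                         split == "train")
  axes <- suppressWarnings(derive_axis_pair(ctrl, heat))
  stressed <- select_samples(ds, genotype == "N2", treatment == "heat")
  proj <- project(stressed, axes$H)
  ablated_rho <- abs(cor(proj$score, proj$t_heat, method = "spearman"))

  # with the stress loadings planted (identical seed and design), the same
  # axis tracks exposure duration almost perfectly; without them most of
  # that association disappears
  run <- default_run()
  ph <- run$projections$H
  sel <- ph$genotype == "N2" & ph$treatment == "heat"
  planted_rho <- abs(cor(ph$score[sel], ph$t_heat[sel], method = "spearman"))
  expect_gt(planted_rho, 0.9)
  expect_lt(ablated_rho, planted_rho - 0.3)
})

test_that("recovery decay rates respond to the dose-dependent slowing", {
  fit_rates <- function(lambda) {
    cfg <- sim_config(lambda = lambda)
    rho_ref <- exp(cfg$rho0_meanlog)
    vapply(c(2, 3, 4, 6), function(th) {
      t_rec <- seq(0.5, 4, by = 0.5)
      u <- simulate_dose(rep(th, length(t_rec)), t_rec, rho_ref, cfg)
      -unname(coef(lm(log(u) ~ t_rec))[2])
    }, numeric(1))
  }
  rates0 <- fit_rates(0)
  # without slowing all series decay at the common base rate
  expect_equal(rates0, rep(exp(sim_config()$rho0_meanlog), 4),
               tolerance = 1e-6)
  rates <- fit_rates(1.5)
  # with slowing, longer exposures decay materially more slowly
  expect_lt(rates[4], 0.7 * rates[1])
})

test_that("survival generator links lifespan ratios to recovery rates", {
  cfg <- small_config()
  sim <- simulate_expression(cfg)
  sv1 <- simulate_survival(cfg, sim$truth)
  sv2 <- simulate_survival(cfg, sim$truth)
  expect_identical(sv1$table, sv2$table)
  g <- sv1$truth$genotypes
  expect_true(all(g$r_true > 0 & g$r_true <= 1.1))
  # the fastest recoverers are nearly unaffected
  fast <- which.max(g$rho0)
  expect_gt(g$r_true[fast], 0.7)
  # population-level effect: heat arm dies earlier on average
  expect_lt(mean(sv1$table$day[sv1$table$treatment == "heat"]),
            mean(sv1$table$day[sv1$table$treatment == "control"]))
  # per-arm size matches the configured number of scored animals
  expect_identical(sum(sv1$table$genotype == g$genotype[1] &
                         sv1$table$treatment == "control"),
                   as.integer(cfg$n_worms))
})

test_that("configuration rejects invalid parameters", {
  expect_error(sim_config(noise_sd = -1), "scale parameters")
  expect_error(sim_config(low_expression_fraction = 1.2), "\\(0, 1\\)")
  expect_error(sim_config(nonsense = 1), "unknown")
})
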
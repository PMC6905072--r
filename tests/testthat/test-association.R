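test_that("spearman correlation handles monotone, reversed and tied inputs", {
  expect_equal(spearman_cor(1:3, c(2, 4, 6))$rho, 1)
  expect_equal(spearman_cor(1:3, c(6, 4, 2))$rho, -1)
  r <- spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)
  expect_identical(r$method, "exact")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  expect_error(spearman_cor(1:5, rep(1, 5)), "constant")
  # missing pairs are dropped
  expect_identical(spearman_cor(c(1:4, NA), c(2, 4, 6, 8, 1))$n, 4L)
})

test_that("exact permutation p-value equals brute-force enumeration", {
  # n = 4: all 24 permutations enumerated independently in R
  x <- c(1, 2, 3, 4)
  for (y in list(c(1, 3, 2, 4), c(4, 1, 3, 2), c(2, 2, 3, 1))) {
    expect_equal(spearman_cor(x, y)$p, spearman_perm_oracle(x, y),
                 tolerance = 1e-12, label = paste(y, collapse = ","))
  }
  expect_equal(spearman_cor(x, c(1, 3, 2, 4))$p, 1 / 3, tolerance = 1e-12)
  # n = 6 with ties, against the same oracle
  x6 <- c(2, 5, 1, 4, 6, 3)
  y6 <- c(1, 1, 2, 5, 6, 4)
  expect_equal(spearman_cor(x6, y6)$p, spearman_perm_oracle(x6, y6),
               tolerance = 1e-12)
})

test_that("large-sample p-values follow the t approximation", {
  set.seed(13)
  x <- rnorm(25); y <- x + rnorm(25, sd = 2)
  r <- spearman_cor(x, y)
  expect_identical(r$method, "t-approximation")
  tstat <- r$rho * sqrt((r$n - 2) / (1 - r$rho^2))
  expect_equal(r$p, 2 * pt(-abs(tstat), r$n - 2), tolerance = 1e-12)
  expect_equal(spearman_cor(1:20, (1:20)^2)$p, 0)
})

test_that("top contributors rank by absolute loading with signed labels", {
  l <- setNames(c(0.9, -0.8, 0.1, 0.05, -0.02, 0.01, 0.015, 0.012,
                  -0.011, 0.008) / 1.5, sprintf("g%02d", 1:10))
  ax <- manual_axis(l)
  top <- top_contributors(ax, fraction = 0.2)
  expect_identical(top$gene_id, c("g01", "g02"))
  expect_identical(top$direction, c("up", "down"))
  # 5% of 100 genes is exactly 5 genes
  ax100 <- manual_axis(setNames(seq(1, 0.01, length.out = 100),
                                sprintf("g%03d", 1:100)))
  expect_identical(nrow(top_contributors(ax100, 0.05)), 5L)
  # one-sided tails restrict the candidate pool
  expect_true(all(top_contributors(ax, 0.2, tail = "down")$loading < 0))
})

test_that("the stress axis has more upregulated than downregulated top genes", {
  run <- default_run()
  top <- top_contributors(run$axes$H, fraction = 0.05)
  tab <- table(factor(top$direction, levels = c("down", "up")))
  expect_gt(tab[["up"]], tab[["down"]])
})

test_that("hypergeometric p-values equal exhaustive enumeration up to N = 25", {
  for (N in c(5, 10, 17, 25)) {
    for (K in c(1, floor(N / 3), N - 1)) {
      for (n in c(1, floor(N / 2), N)) {
        for (k in max(0, n + K - N):min(K, n)) {
          expect_equal(resilax:::hypergeom_upper(k, K, N, n),
                       hyper_upper_enum(k, K, N, n), tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("enrichment matches closed-form counts and applies the filters", {
  universe <- sprintf("g%02d", 1:20)
  sets <- structure(list(hit = universe[1:5], small = universe[1:3],
                         off = universe[11:16]),
                    class = "gene_set_collection")
  query <- universe[1:5]
  res <- hypergeometric_enrichment(query, sets, universe)
  hit <- res[res$set_name == "hit", ]
  # drawing all 5 marked genes in 5 draws from 20: p = 1 / C(20, 5)
  expect_equal(hit$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(hit$passes_filter)
  # category size filter: n > 3 required no matter how extreme p is
  small <- res[res$set_name == "small", ]
  expect_false(small$passes_filter)
  # zero overlap has upper-tail probability 1
  expect_equal(res[res$set_name == "off", ]$p, 1)
  expect_error(hypergeometric_enrichment(character(0), sets, universe), "empty")
  expect_error(hypergeometric_enrichment("gX", sets, universe),
               "outside the universe")
})

test_that("gene-list overlap test applies the strict reporting filter", {
  universe <- sprintf("g%03d", 1:100)
  res <- overlap_test(universe, universe, universe)
  expect_equal(res$p, 1)
  # an overlap of exactly 10 fails the > 10 rule regardless of p
  q <- universe[1:10]
  res10 <- overlap_test(q, q, universe)
  expect_lt(res10$p_bonferroni, 0.001)
  expect_false(res10$passes_filter)
  res11 <- overlap_test(universe[1:11], universe[1:11], universe)
  expect_true(res11$passes_filter)
})

test_that("random gene lists almost never pass the overlap filter", {
  set.seed(41)
  universe <- sprintf("g%04d", 1:1000)
  hits <- vapply(seq_len(1000), function(i) {
    q <- sample(universe, 50)
    r <- sample(universe, 50)
    overlap_test(q, r, universe)$passes_filter
  }, logical(1))
  expect_lt(mean(hits), 0.005)
})

test_that("resilience predicts thermotolerance in the simulated panel", {
  run <- default_run()
  expect_lt(run$correlation$rho, 0)
  expect_lt(run$correlation$p, 0.05)
})
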
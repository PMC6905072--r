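# shared fixtures and independent oracles for the test suite

# memoised default-condition study and pipeline run (the heavy objects are
# computed once per test session and reused across files)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_study <- function() cached("study", simulate_study(sim_config()))

default_run <- function() cached("run", suppressMessages(
  run_pipeline(list(seed = 42))))

# small, fast study used where full size is unnecessary
small_config <- function(...) sim_config(n_genes = 300, n_genotypes = 10,
                                         seed = 7L, ...)

# tiny expression fixture with hand-set values
tiny_dataset <- function() {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), genotype = "N2",
                     treatment = "control", t_dev = c(46, 48), t_heat = 0,
                     t_rec = 0, split = "train", stringsAsFactors = FALSE)
  expression_dataset(m, meta)
}

# axis with explicit loadings in a space with identity standardization
manual_axis <- function(loadings, gene_ids = names(loadings), name = "custom") {
  st <- structure(list(gene_ids = gene_ids,
                       mean = rep(0, length(gene_ids)),
                       sd = rep(1, length(gene_ids)),
                       source_tag = "manual"),
                  class = "standardizer")
  resilax:::new_stress_axis(loadings, gene_ids, st, component_index = 1L,
                            variance_explained = NA_real_, name = name)
}

# brute-force upper-tail hypergeometric probability by direct enumeration of
# the probability mass function, independent of phyper
hyper_upper_enum <- function(k, K, N, n) {
  ks <- max(0, n + K - N):min(K, n)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}

# brute-force two-sided permutation p-value for the Spearman correlation,
# enumerating permutations recursively in R (small n only)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

spearman_perm_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- all_permutations(length(y))
  rhos <- apply(perms, 1L, function(p) cor(rx, ry[p]))
  mean(abs(rhos) >= obs - 1e-9)
}
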
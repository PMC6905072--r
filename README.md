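# resilax

Quantifying transcriptome resilience to heat stress — and using it to
predict thermotolerance.

## What it does

A heat pulse moves the expression of thousands of genes at once, and the
speed at which a genotype's transcriptome leaves that stressed state again
predicts how well the animal survives the stress in the long run. `resilax`
turns genome-wide log2 expression time series into a handful of
interpretable scalar scores:

1. **Developmental axis `D`** — PCA on unperturbed, age-synchronized time
   series; the component tracking age captures stress-independent temporal
   expression change.
2. **Heat-stress axis `H`** — the analogous component of a heat-exposure
   time course, with the developmental direction removed by Gram–Schmidt
   orthogonalization and re-normalized:

   `H = (Ĥ − (Ĥ·D) D) / ‖Ĥ − (Ĥ·D) D‖`

   The projection *h* of any sample on `H` measures how stressed its
   transcriptome looks: *h* rises with exposure duration, saturates under
   long exposure, and relaxes back during recovery — slower after harsher
   stress.
3. **Genetic axes `GD` / `GH`** — the same construction across an
   inbred-line panel (baseline genotype differences removed from the
   stressed-state differences). The projection *gh* of a genotype's
   recovery sample on `GH` is its **transcriptional resilience** score:
   high *gh* = still far from baseline = poor resilience.
4. **Thermotolerance link** — per-genotype lifespan assays (control vs
   heat arm) are summarized by the mean-lifespan ratio heat/control and a
   per-genotype logrank test with Benjamini–Hochberg FDR control; the
   resilience score is then rank-correlated (Spearman) with the lifespan
   ratio. Slow transcriptional recoverers lose the most lifespan, so the
   correlation is negative.

Supporting machinery: strict low-expression filtering at mean log2
intensity 4.5; train-set standardizers reused for every projection;
hypergeometric gene-set enrichment of top axis contributors (top 5% by
|loading|) with Bonferroni correction; gene-list overlap tests; a
subset-SD resampling analysis comparing genotype scatter with replicate
scatter; and a fully seeded synthetic-data generator that plants known
developmental, dose, genotype and lifespan structure so every stage is
testable end to end. Everything is driven either from R or through
`run_pipeline()` with a YAML/list configuration.

## Worked example

```r
library(resilax)
res <- run_pipeline(list(seed = 42))   # simulates its own study

res$axes$H
#> stress_axis 'H': 1377 genes, from PC2 (11.6% of training variance); confound overlap 0.150

res$correlation
#> Spearman rho = -0.918, p = 6.97e-17 (n = 40, t-approximation)

res$survival$counts
#> $n_significant
#> [1] 35
#> $n_not
#> [1] 6

res$subset_sd$heat
#> subset_sd_report: 5000 subsets of size 6 (heat)
#>   subset SD: median 16.32 [4.841, 29.14]
#>   reference SD 0.9373 at percentile 0.0
```

Reading the output: of 2000 simulated genes, 1377 pass the expression
filter; the heat-stress axis comes from the second principal component of
the stress training data and overlaps the developmental axis by 0.150
before orthogonalization (zero after). Genotype resilience scores
(`res$resilience`) strongly predict the planted thermotolerance: rho =
−0.918 means the genotypes that stay transcriptionally stressed after the
pulse are the ones whose lifespan the stress shortens most. 35 of 41 lines
are significantly affected by the stress at FDR < 0.05, and the
genotype-to-genotype scatter of stress scores dwarfs replicate scatter
(reference replicate SD 0.94 sits at the 0th percentile of 5000 random
panel subsets, median SD 16.3) — the panel genuinely varies in its stress
response.

The least resilient lines are also the least thermotolerant:

```r
head(res$resilience[order(-res$resilience$gh_recovery), ], 3)
#>    genotype gh_recovery  gh_heat
#> 18    RIL18    41.22577 42.42740
#> 19    RIL19    39.94442 34.11596
#> 39    RIL39    32.59440 37.37383

th <- res$survival$thermotolerance
head(th[order(th$ratio), ], 3)
#>    genotype mean_control mean_heat     ratio
#> 20    RIL19     17.61290  7.451613 0.4230769
#> 19    RIL18     17.19355  7.290323 0.4240150
#> 40    RIL39     16.64516  7.741935 0.4651163
```

To analyse your own data instead, point the configuration at a
tab-delimited expression matrix, a sample sheet (`sample_id`, `genotype`,
`treatment`, `t_dev`, `t_heat`, `t_rec`, `split`) and a cumulative-death
lifespan table:

```r
run_pipeline(list(seed = 1,
                  input = list(expression = "expr.tsv",
                               metadata = "meta.tsv",
                               survival = "lifespan.tsv"),
                  out_dir = "results/"))
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`.

## Documentation

The methods vignette (`vignettes/transcriptome-resilience.Rmd`) documents
the model behind each axis, the generator's assumptions and defaults, the
numerical choices (tolerances, tie handling, degenerate inputs), and known
limitations.
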
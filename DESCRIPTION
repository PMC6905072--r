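Package: resilax
Title: Transcriptome Resilience Axes and Thermotolerance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers quantitative axes of transcriptome dynamics from
    log2 gene-expression time series by principal component analysis with
    confound-removing orthogonalization: a developmental axis from
    unperturbed samples, a heat-stress axis from stressed samples with the
    developmental signal projected out, and analogous genotype-level axes
    for panels of inbred lines. Projecting samples onto these axes yields
    scalar stress and resilience scores that can be linked to
    thermotolerance measured from lifespan assays (logrank tests with
    false-discovery-rate control, lifespan ratios, rank correlations).
    Includes gene-set enrichment by hypergeometric tests, resampling-based
    variability analyses, and a synthetic-data generator that plants known
    developmental, stress-dose, and genotype structure for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
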
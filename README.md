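# metamethyl

**EWAS meta-analysis of age in skeletal-muscle methylomes, and a muscle
epigenetic clock.**

Skeletal muscle ages epigenetically: thousands of CpG sites gain or lose DNA
methylation across the adult lifespan, but any single cohort is too small,
too narrow in age range, or too array-specific to map them reliably.
`metamethyl` is an R package plus analysis workflow for the field-standard
answer to that problem: run a covariate-adjusted EWAS of age separately in
each cohort, correct each cohort's test statistics for bias and inflation,
combine cohorts by fixed-effects inverse-variance meta-analysis, call
differentially methylated regions (DMRs) by kernel smoothing, characterize
them functionally, and train a penalized-regression age predictor
("epigenetic clock") with honest leave-one-dataset-out evaluation.

It is aimed at epigenomics researchers who have per-cohort beta matrices and
sample sheets in hand (the pipeline starts at beta values; IDAT
preprocessing is out of scope) and want a tested, reproducible
implementation of the whole chain — including a synthetic multi-cohort
generator so every stage can be exercised and benchmarked without any
controlled-access data.

## The statistics at the core

Per cohort, for each CpG *g* with methylation fraction (beta) *β*:

- OLS (or GLS with a consensus within-subject correlation ρ for repeated
  measures) of *β* on age plus available covariates; empirical-Bayes
  variance moderation: s̃² = (d₀s₀² + ds²)/(d₀ + d), moderated t on d₀+d df.
- Empirical-null correction: signed probit z-scores modeled as a constrained
  3-component Gaussian mixture; the null component's mean μ₀ (bias) and sd
  σ₀ (inflation) rescale every statistic, z′ = (z−μ₀)/σ₀.
- Meta-analysis: wᵢ = 1/seᵢ², b̄ = Σwᵢbᵢ/Σwᵢ, se = (Σwᵢ)^(−1/2), with
  Cochran's Q and I² for heterogeneity; CpGs in ≥6/10 cohorts; DMPs at
  BH FDR < 0.005.
- DMRs: Gaussian-kernel smoothing of z² (λ = 1 kb, σ = λ/2) with
  Satterthwaite χ² p-values; significant CpGs within λ merge; regions must
  pass Fisher, Stouffer and harmonic-mean-FDR thresholds (all 0.005).
- Enrichment: CpG-level χ² with Pearson residuals for genomic context;
  Wallenius noncentral hypergeometric (CpG-count-bias-corrected) for gene
  sets; 2×2 χ² for overlap with transcriptome/proteome DE lists.
- Clock: beta-mixture quantile calibration to a gold-standard cohort,
  elastic net on transformed age F(age) = log(age+1) − log(21) below 20
  years and (age−20)/21 above, leave-one-dataset-out accuracy.

## Worked example

```r
library(metamethyl)

# a synthetic 10-cohort study: 859 samples, 10,000 probes, 50 spiked
# age-effect blocks at ~0.8% methylation change per decade
cfg <- sim_config(n_probes = 10000, n_blocks = 50L,
                  dmr_block_len = c(3L, 8L), slope_scale = 0.0008,
                  slope_jitter = 0)
toy <- build_toy_annotation(cfg, seed = 11)
sim <- simulate_multicohort(toy, cfg, seed = 11)

pipe <- run_age_meta_pipeline(sim$datasets, toy$annotation, seed = 11)
pipe$dmps$n
#> [1] 211
round(c(pipe$dmps$pct_hypo, pipe$dmps$pct_hyper), 1)
#> [1] 58.8 41.2
round(pipe$dmps$mean_pct_per_decade, 2)
#>  hypo hyper
#>  0.80  0.74
score_dmrs_against_truth(pipe$dmrs, sim$truth)[c("sensitivity", "n_false")]
#> $sensitivity
#> [1] 1
#> $n_false
#> [1] 0
```

211 of the ~10,000 meta-analyzed CpGs are DMPs at FDR < 0.005, the called
DMRs recover all 50 spiked blocks with no false region, the mean effect
among hypo-DMPs (0.80% per decade) matches the 0.8%/decade effect size the
generator injects, and the direction split (58.8% hypo) tracks the
configured 57% hypomethylation excess up to one draw of 50 block signs.

The `analysis/` directory holds the same workflow as numbered drivers —
`01_simulate.R` through `06_clock.R` — each a thin script over the package
functions that prints what it found and writes its tables under `results/`.

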
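---
title: "Methods: EWAS meta-analysis of age in muscle methylomes and the muscle clock"
author: "metamethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EWAS meta-analysis of age in muscle methylomes and the muscle clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metamethyl` implements an end-to-end epigenome-wide association study (EWAS)
meta-analysis of chronological age across heterogeneous DNA methylation
cohorts, the downstream regional and functional analyses, and a penalized
regression "epigenetic clock" for skeletal muscle. This vignette explains the
models, the choices behind them, and what the synthetic benchmark does and
does not demonstrate.

## The measurement model

Methylation arrives as *beta values*: per-CpG methylation fractions in
$[0,1]$, one matrix (CpG $\times$ sample) per cohort, with a sample sheet
carrying age and the adjustment covariates (sex, BMI, diabetes status, batch,
time point) and a subject id connecting repeated measures. Cohorts differ in
array generation (27k-, 450k- and EPIC-like probe content), age
distribution, sex composition, and design, which is precisely why the
analysis is per-cohort-then-meta rather than pooled: normalizing cohorts
together when age is confounded with cohort would distort the signal.

## Per-cohort EWAS

Each cohort's EWAS regresses the beta value of every CpG on age, adjusting
for whichever covariates the cohort actually has (constant or absent
covariates are dropped with a logged warning; an all-male cohort simply has
no sex term). We model on the beta scale because effects are reported as
percent methylation per decade; an M-value analysis is a trivial user-side
transform but is not the default. Repeated measures enter through a single
consensus within-subject correlation, estimated on a probe subsample by
Fisher-z-averaging per-probe estimates with a 15% trimmed mean, followed by a
generalized least squares fit per probe under an exchangeable within-subject
correlation; with no repeated measures this reduces exactly to OLS. These
steps are delegated to `limma` (`lmFit`, `duplicateCorrelation`), the
standard engine for array linear models.

Per-probe residual variances are moderated by empirical Bayes: a scaled
inverse-chi-square prior $(d_0, s_0^2)$ fitted by moment matching on
$\log s^2$ (`limma::squeezeVar`), posterior variances
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and moderated t statistics on
$d_0 + d$ degrees of freedom. Probes with zero residual variance are flagged
degenerate, get missing statistics, and are excluded from the empirical-null
fit.

### Bias and inflation correction

Unmeasured confounding (cell composition, batch structure) shifts and
inflates EWAS test statistics. We transform each probe's two-sided moderated
p-value to a signed probit z-score and model the z distribution as a
three-component Gaussian mixture: a central null $N(\mu_0, \sigma_0^2)$
(weight initialized at 0.9) flanked by a negative-mean and a positive-mean
alternative component. Constraints keep the alternatives honest: their means
must sit at least one null-sd away from $\mu_0$ on either side (otherwise an
alternative can impersonate the null and split its weight) and their sds must
be at least $\sigma_0$. The EM runs from 10 seeded restarts; if none attains
a finite converged likelihood the null falls back to the median/MAD, flagged.
Corrected statistics are $z' = (z - \mu_0)/\sigma_0$ with
$p' = 2\Phi(-|z'|)$.

**Corrected standard errors.** The corrected standard error fed to the
meta-analysis is defined as $se' = |b| / |z'|$, so that $b / se'$ reproduces
the corrected z exactly on the effect scale (with $se \cdot \sigma_0$ as the
$b = 0$ limit). The alternative of rescaling $se' = se\cdot\sigma_0$ leaves
the pooled statistic carrying the t-distribution tails of the moderated
statistic — with small cohorts and small prior df this measurably inflates
the pooled null (we observed pooled z sd $\approx 1.15$ and spurious DMPs on
null simulations). Rebuilding the standard error from the corrected p-value
is also how inverse-variance meta inputs are conventionally derived from
corrected summary statistics.

## Meta-analysis

CpGs present (finite effect and standard error) in at least 6 of the 10
cohorts are pooled by fixed-effects inverse variance weighting
($w_i = 1/se_i^2$); heterogeneity is quantified by Cochran's
$Q = \sum w_i (b_i - \bar b)^2$ and $I^2 = \max(0, (Q - (k-1))/Q)$, reported
but never used as a filter. Benjamini–Hochberg FDR is computed once over the
coverage-filtered universe, and CpGs at FDR < 0.005 are differentially
methylated positions (DMPs). Hypo- vs hyper-methylation is decided by the
sign of the pooled effect, with exact zeros (ties) counted as hyper —
arbitrary, documented, and of measure zero in practice. Sensitivity re-runs
(dropping cohorts, or samples matching a predicate such as diabetes status)
repeat the whole pipeline on the subset and report the correlation of pooled
effects and the DMP cross-tabulation against the full run.

## DMR calling

Regions are detected by Gaussian-kernel smoothing of the squared pooled
z-scores along each chromosome: $K_{ij} = \exp(-(x_i-x_j)^2 / 2\sigma^2)$
with bandwidth $\lambda = 1000$ bp and $\sigma = \lambda/C$, $C = 2$,
truncated at $3\sigma$ (numerically indistinguishable from the full kernel in
the clustered-CpG geometry; tested against the untruncated oracle). Under the
null $z^2 \sim \chi^2_1$, so the kernel average $S_i$ has mean 1 and the
two-moment Satterthwaite match gives effective df
$\nu_i = (\sum_j K_{ij})^2 / \sum_j K_{ij}^2$ and
$p_i = P(\chi^2_{\nu_i} > \nu_i S_i)$. CpGs significant after BH correction
of the smoothed p-values (FDR < 0.005) are aggregated greedily, with a gap
larger than $\lambda$ starting a new region and regions below 2 CpGs
discarded (a 1-CpG "region" is a DMP). Each region is then summarized by
three statistics over its members' meta-analysis results — Fisher's
$-2\sum\ln p$ (BH-adjusted across candidate regions; the multiplicity
interpretation of the "Fisher multiple comparison statistic" is ours),
the Stouffer score $\sum z_j/\sqrt{m}$, and the harmonic mean of the member
FDRs — and emitted only if all three fall below 0.005. The region effect is
the inverse-variance-weighted mean of member effects; mixed-sign regions are
assigned by its sign, and the member sign split is retained.

## Enrichment and integration

Context enrichment counts *CpGs* (members of hypo-DMRs, of hyper-DMRs, or
neither) across the levels of a genomic category — CpG-island context
(island / shore ±2 kb / shelf 2–4 kb / open sea >4 kb, computed from the
distance to the nearest island edge), chromatin state (containment, with the
smallest-start interval winning ties and `Quies` as the default off-track
state), or CTCF/EZH2 binding — in a Pearson chi-square with per-cell
residuals $(O-E)/\sqrt E$. CpG-level counting makes the margins well-defined
when regions straddle category boundaries. Categories with expected counts
below 1 are pooled into `other`.

Gene-set enrichment must correct for CpG-count bias: genes with more
measured CpGs are more likely to harbour a DMR under any null. Each set is
tested with the Wallenius noncentral hypergeometric upper tail whose single
odds parameter is the ratio of mean per-gene CpG counts inside vs outside
the set; with equal counts this reduces exactly to the central
hypergeometric. The pmf is evaluated from its integral representation (after
the substitution $u = t^{1/D}$ and peak normalization, stable for large
problems); tests verify it against exhaustive weighted-draw recursion.

Genes with at least one DMR are differentially methylated genes (DMGs),
carrying a direction profile (some genes harbour both hypo- and hyper-DMRs).
Overlap with external differential-expression lists is a 2×2 chi-square over
an explicit, caller-supplied gene universe (the array-gene universe is the
natural choice; the package takes no silent position), with a Haldane 0.5
correction for empty cells in the odds ratio. Relationship classification
calls a DMR–gene pair *negative* when the expression and methylation signs
oppose, stratified by whether the DMR's member CpGs lie predominantly in
actively transcribed chromatin (`Tx`, `TxWk`), where the positive pattern is
biologically expected.

## The muscle clock

Datasets are reduced to their shared probes, then calibrated to a
gold-standard dataset — by default the cohort with the widest age range —
via beta-mixture quantile matching: a 3-component beta mixture
(unmethylated / hemimethylated / methylated) is fitted to each sample by EM
with a moment-matching M-step, every probe is assigned to its most likely
state, and values are mapped through the state's fitted CDF into the
reference state's inverse CDF. The map is monotone within each state,
near-identity for data already distributed like the reference, and close to
idempotent. Mixture parameters are estimated on evenly spaced order
statistics (at most 1000 values), which makes the fit deterministic given
the value distribution and independent of probe order.

Age is transformed by $F(a) = \log(a+1) - \log(a_{adult}+1)$ below the adult
knot and $(a - a_{adult})/(a_{adult}+1)$ above it, with $a_{adult} = 20$
years (the standard human knot; exposed as a parameter and stored in the
model). The clock is an elastic net ($\alpha = 0.5$, penalty chosen by
internal 10-fold CV minimizing squared error, folds derived from the seed)
of $F(\text{age})$ on the calibrated betas; only nonzero-coefficient probes
are retained. Accuracy is estimated by leave-one-dataset-out
cross-validation: the held-out cohort influences neither the reference
choice (made among training cohorts only) nor the penalty; it is calibrated
to the training reference and predicted cold. Missing model probes at
prediction time are imputed with reference probe means, with a hard error
above 20% missing.

## The synthetic study

The generator emulates the structure of published muscle methylome
meta-analyses: 10 cohorts whose sample sizes (22–282 samples, 859 total),
age windows (18–89 years), sex mixes, array coverages (EPIC-like 0.95,
450k-like 0.55, 27k-like 0.12 of the toy universe), batch structure,
repeated measures, and diabetes cases mirror the heterogeneity of real
cohort tables. Betas follow a latent-logistic model
$y = \alpha_g + \beta_g(\text{age}-50) + \gamma_g^\top x + u_{subject} +
b_{batch} + \varepsilon$ squashed through the inverse logit and clipped to
$(0.001, 0.999)$, with island-dependent bimodal baselines. Age effects are
spiked in blocks of 2–10 adjacent CpGs; 57% of blocks lose methylation with
age and effects default to 0.0008 beta/year (≈0.8%/decade), matching the
magnitude and slight hypomethylation excess reported for ageing muscle.
Truth slopes are recorded on the beta scale at each probe's baseline (delta
method: $\beta_{beta} = \beta_{latent}\, p(1-p)$). Latent noise
($\sigma = 0.15$), subject ($0.08$) and batch ($0.05$) sds were chosen once
as realistic values for array data. Per-cohort streams are seeded by hashing
(dataset id, seed), so results do not depend on cohort iteration order, and
every stage is bit-identical under a fixed seed.

What the generator does *not* emulate: probe-level spatial correlation
beyond the spiked blocks, cell-composition drift with age, sex-chromosome
dosage, raw-intensity artefacts, or annotation errors. Passing benchmarks
therefore demonstrate the statistical machinery — calibration under the
null, FDR control, regional recovery, bias correction, clock
generalization — not robustness to every failure mode of real arrays.

## Problem sizes and benchmark settings

All replicated studies run at 10,000 probes. Null-calibration and
FDR-control experiments use the reduced-size cohort design
(`scaled_cohort_design()`, ~190 samples) for 20 replicates each; the
DMR-recovery benchmark uses the full-size design (859 samples) with 50
spiked blocks of 3–8 CpGs at 0.0008 beta/year; the clock benchmark uses 8
cross-sectional cohorts (204 samples) with ~300 true clock CpGs of 0.001
beta/year among 5,000 probes. Empirical-null recovery is checked on a
$3\times3$ grid of bias/inflation at 50,000 z-scores with 10% true signal.
These sizes were chosen so each property is measured with useful precision
while a full run of the suite stays comfortably interactive.

## Numerical choices and degenerate inputs

- Beta values exactly 0/1 are clipped to $[10^{-6}, 1-10^{-6}]$ before
  logit-scale operations; p-values are floored at the smallest positive
  double before log-combination.
- Probes without genomic coordinates are retained for DMP-level statistics
  but excluded from DMR calling and context enrichment.
- Zero-se cohorts are excluded from a probe's meta-analysis; $k = 1$ probes
  get $Q = 0$, $I^2 = 0$ by convention.
- The chromatin-state tie-break (smallest interval start) and the
  hyper-assignment of exact-zero effects are arbitrary but deterministic and
  tested.
- The beta-mixture M-step is moment matching rather than full MLE, so the
  likelihood is not guaranteed monotone; the best-likelihood iterate is
  tracked and returned.

## Known limitations

Fixed-effects meta only (no random-effects or meta-regression); no surrogate
variable or cell-composition deconvolution; gene sets are user-supplied (no
bundled GO/KEGG/Reactome catalogs); the calibration reference must contain
all three methylation states; the Wallenius approximation uses a single
odds parameter per set. The genome-build question is deliberately left to
the user: annotation is an input, and the package takes no position on
hg19 vs hg38.
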
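#' Coverage filter across cohorts
#'
#' Probes are meta-analyzed only when a finite effect and standard error are
#' available in at least `min_cohorts` cohorts; array designs differ, so the
#' probe overlap between cohorts is imperfect.
#'
#' @param ewas_list List of `EwasResult` data frames (one per cohort).
#' @param min_cohorts Minimum number of contributing cohorts (default 6).
#' @return Character vector of retained probe ids.
#' @export
filter_coverage <- function(ewas_list, min_cohorts = 6L) {
  stopifnot(min_cohorts >= 1)
  ids <- unlist(lapply(ewas_list, function(e) {
    e$probe_id[is.finite(e$b) & is.finite(e$se_corr %||% e$se) &
                 (e$se_corr %||% e$se) > 0]
  }))
  tab <- table(ids)
  sort(names(tab)[tab >= min_cohorts])
}

#' Fixed-effects inverse-variance-weighted meta-analysis of one probe
#'
#' `w_i = 1/se_i^2`, `b = sum(w b) / sum(w)`, `se = 1/sqrt(sum w)`,
#' `z = b/se`, two-sided normal p. Cohorts with `se = 0` are excluded.
#'
#' @param b Per-cohort effects.
#' @param se Per-cohort standard errors.
#' @return List `b_meta`, `se_meta`, `z_meta`, `p_meta`, `k`.
#' @export
ivw_meta <- function(b, se) {
  keep <- is.finite(b) & is.finite(se) & se > 0
  b <- b[keep]; se <- se[keep]
  if (length(b) == 0) {
    return(list(b_meta = NA_real_, se_meta = NA_real_, z_meta = NA_real_,
                p_meta = NA_real_, k = 0L))
  }
  w <- 1 / se^2
  b_meta <- sum(w * b) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  z <- b_meta / se_meta
  list(b_meta = b_meta, se_meta = se_meta, z_meta = z,
       p_meta = 2 * pnorm(-abs(z)), k = length(b))
}

#' Cochran's Q and I-squared heterogeneity
#'
#' `Q = sum w_i (b_i - b_meta)^2` with `I2 = max(0, (Q - (k-1))/Q)`;
#' `I2 = 0` by convention when `k = 1` or `Q = 0`.
#'
#' @param b,se Per-cohort effects and standard errors.
#' @param b_meta Fixed-effects pooled estimate.
#' @return List `Q`, `I2`.
#' @export
heterogeneity <- function(b, se, b_meta) {
  keep <- is.finite(b) & is.finite(se) & se > 0
  b <- b[keep]; se <- se[keep]
  k <- length(b)
  if (k <= 1) return(list(Q = 0, I2 = 0))
  Q <- sum((b - b_meta)^2 / se^2)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  list(Q = Q, I2 = I2)
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' Thin wrapper over `p.adjust(..., method = "BH")`, kept as a named surface
#' because the 0.005 FDR threshold defines the DMP call.
#'
#' @param p Vector of p-values in (0, 1\].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) p.adjust(p, method = "BH")

#' Meta-analyze per-cohort EWAS results across cohorts
#'
#' Applies the coverage filter, pools corrected effects by fixed-effects
#' inverse-variance weighting, computes Cochran's Q / I-squared, BH FDR over
#' the filtered probe universe, and a per-cohort direction string (`+`, `-`,
#' or `?` for cohorts whose array lacks the probe).
#'
#' @param ewas_list List of `EwasResult` data frames.
#' @param min_cohorts Coverage filter threshold.
#' @return A `MetaResult` data frame: `probe_id`, `k`, `b_meta`, `se_meta`,
#'   `z_meta`, `p_meta`, `q_meta`, `Q`, `I2`, `direction`.
#' @export
run_meta <- function(ewas_list, min_cohorts = 6L) {
  probes <- filter_coverage(ewas_list, min_cohorts)
  if (length(probes) == 0) stopf("no probe passes the coverage filter")
  K <- length(ewas_list)
  B <- SE <- matrix(NA_real_, length(probes), K)
  for (j in seq_len(K)) {
    e <- ewas_list[[j]]
    se_j <- e$se_corr %||% e$se
    idx <- match(probes, e$probe_id)
    B[, j] <- e$b[idx]
    SE[, j] <- se_j[idx]
  }
  SE[!is.finite(SE) | SE <= 0] <- NA_real_
  B[!is.finite(B)] <- NA_real_
  miss <- is.na(B) | is.na(SE)
  B[miss] <- NA_real_; SE[miss] <- NA_real_
  W <- 1 / SE^2
  sw <- rowSums(W, na.rm = TRUE)
  b_meta <- rowSums(W * B, na.rm = TRUE) / sw
  se_meta <- 1 / sqrt(sw)
  z <- b_meta / se_meta
  k <- rowSums(!miss)
  Q <- rowSums(W * (B - b_meta)^2, na.rm = TRUE)
  I2 <- ifelse(k > 1 & Q > 0, pmax(0, (Q - (k - 1)) / Q), 0)
  dir_chr <- matrix("?", length(probes), K)
  dir_chr[!miss & B > 0] <- "+"
  dir_chr[!miss & B <= 0] <- "-"
  res <- data.frame(
    probe_id = probes, k = k, b_meta = b_meta, se_meta = se_meta,
    z_meta = z, p_meta = 2 * pnorm(-abs(z)), Q = Q, I2 = I2,
    direction = apply(dir_chr, 1, paste, collapse = ""),
    stringsAsFactors = FALSE)
  res$q_meta <- bh_fdr(res$p_meta)
  res[, c("probe_id", "k", "b_meta", "se_meta", "z_meta", "p_meta",
          "q_meta", "Q", "I2", "direction")]
}

#' Call differentially methylated positions (DMPs)
#'
#' Probes with meta-analysis FDR below the threshold. The summary reports the
#' hypo/hyper split (hypo strictly negative pooled effect; ties count as
#' hyper) and the mean absolute change per decade of life, in percent
#' methylation, by direction.
#'
#' @param meta A `MetaResult` data frame.
#' @param q_threshold FDR threshold (default 0.005).
#' @return A `DmpCall` list: `dmps` (subset of `meta`), `n`, `n_hypo`,
#'   `n_hyper`, `pct_hypo`, `pct_hyper`, `mean_pct_per_decade` (named by
#'   direction).
#' @export
call_dmps <- function(meta, q_threshold = 0.005) {
  dmps <- meta[!is.na(meta$q_meta) & meta$q_meta < q_threshold, , drop = FALSE]
  hypo <- dmps$b_meta < 0
  n <- nrow(dmps)
  mean_pd <- c(
    hypo = if (any(hypo)) mean(abs(dmps$b_meta[hypo])) * 10 * 100 else NA_real_,
    hyper = if (any(!hypo)) mean(abs(dmps$b_meta[!hypo])) * 10 * 100 else NA_real_)
  list(dmps = dmps, n = n,
       n_hypo = sum(hypo), n_hyper = sum(!hypo),
       pct_hypo = if (n > 0) 100 * sum(hypo) / n else NA_real_,
       pct_hyper = if (n > 0) 100 * sum(!hypo) / n else NA_real_,
       mean_pct_per_decade = mean_pd,
       q_threshold = q_threshold)
}

#' Sensitivity re-run of the meta-analysis on a cohort or sample subset
#'
#' Repeats the full per-cohort EWAS + meta-analysis after excluding whole
#' cohorts (`exclude_datasets`) and/or samples matching a predicate on the
#' sample sheet (`sample_filter`, e.g. `function(s) s$t2d == 1` to drop
#' diabetic samples), then reports the concordance with a reference run:
#' correlation of pooled effects and the cross-tabulation of DMP calls.
#'
#' @param datasets List of `MethylationDataset`s.
#' @param reference A `MetaResult` from the full run (for the concordance
#'   report); may be `NULL`.
#' @param exclude_datasets Character vector of cohort ids to drop.
#' @param sample_filter Optional predicate taking a sample sheet and returning
#'   a logical vector of samples to EXCLUDE.
#' @param covariates,min_cohorts,q_threshold,seed Passed to the pipeline.
#' @param min_samples Cohorts reduced below this size are dropped entirely.
#' @return List with `meta`, `dmps`, and `concordance` (`cor_b`,
#'   `dmp_crosstab`) when a reference is given.
#' @export
sensitivity_rerun <- function(datasets, reference = NULL,
                              exclude_datasets = character(0),
                              sample_filter = NULL,
                              covariates = c("sex", "bmi", "t2d", "batch",
                                             "time_point"),
                              min_cohorts = 6L, q_threshold = 0.005,
                              min_samples = 10L, seed = 1L) {
  keep <- !vapply(datasets, function(d) d$dataset_id, "") %in% exclude_datasets
  datasets <- datasets[keep]
  if (!is.null(sample_filter)) {
    datasets <- lapply(datasets, function(d) {
      drop <- sample_filter(d$samples)
      drop[is.na(drop)] <- FALSE
      d$beta <- d$beta[, !drop, drop = FALSE]
      d$samples <- d$samples[!drop, , drop = FALSE]
      d
    })
    datasets <- Filter(function(d) ncol(d$beta) >= min_samples, datasets)
  }
  if (length(datasets) < 2) stopf("fewer than 2 cohorts remain")
  ewas_list <- lapply(datasets, function(d) {
    suppressWarnings(run_ewas(d, covariates, seed = seed))
  })
  meta <- run_meta(ewas_list, min_cohorts = min(min_cohorts, length(datasets)))
  dmps <- call_dmps(meta, q_threshold)
  out <- list(meta = meta, dmps = dmps)
  if (!is.null(reference)) {
    shared <- intersect(meta$probe_id, reference$probe_id)
    i1 <- match(shared, meta$probe_id)
    i2 <- match(shared, reference$probe_id)
    call1 <- meta$q_meta[i1] < q_threshold
    call2 <- reference$q_meta[i2] < q_threshold
    out$concordance <- list(
      cor_b = cor(meta$b_meta[i1], reference$b_meta[i2]),
      dmp_crosstab = table(subset = call1, reference = call2))
  }
  out
}
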
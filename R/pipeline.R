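#' Run the full EWAS-of-age meta-analysis pipeline on a set of cohorts
#'
#' Per-cohort EWAS (covariate adjustment, repeated-measures handling,
#' variance moderation, empirical-null correction), coverage-filtered
#' inverse-variance meta-analysis with heterogeneity, DMP calling at the
#' stringent FDR, and kernel-smoothed DMR calling.
#'
#' @param datasets List of `MethylationDataset`s.
#' @param annotation `ProbeAnnotation` data frame.
#' @param covariates Adjustment covariates for every cohort EWAS.
#' @param min_cohorts Coverage-filter threshold.
#' @param q_threshold DMP FDR threshold.
#' @param dmr_cfg A [dmr_config()].
#' @param correct_null Apply the empirical-null correction per cohort.
#' @param seed Integer seed.
#' @return List `ewas` (per-cohort results), `meta`, `dmps`, `dmrs`.
#' @export
run_age_meta_pipeline <- function(datasets, annotation,
                                  covariates = c("sex", "bmi", "t2d",
                                                 "batch", "time_point"),
                                  min_cohorts = 6L, q_threshold = 0.005,
                                  dmr_cfg = dmr_config(),
                                  correct_null = TRUE, seed = 1L) {
  ewas <- lapply(datasets, function(d) {
    suppressWarnings(run_ewas(d, covariates, correct_null = correct_null,
                              seed = seed))
  })
  meta <- run_meta(ewas, min_cohorts = min(min_cohorts, length(datasets)))
  dmps <- call_dmps(meta, q_threshold)
  dmrs <- call_dmrs(meta, annotation, dmr_cfg)
  list(ewas = ewas, meta = meta, dmps = dmps, dmrs = dmrs)
}

#' Score called DMRs against the simulation truth
#'
#' Block-level sensitivity (fraction of spiked blocks overlapped by at least
#' one emitted DMR), the number of false DMRs (emitted regions overlapping no
#' spiked block), and direction concordance among recovered blocks.
#'
#' @param dmrs DMR data frame from [call_dmrs()].
#' @param truth Truth object from [simulate_multicohort()].
#' @return List `sensitivity`, `n_false`, `direction_concordance`,
#'   `n_recovered`, `n_blocks`.
#' @export
score_dmrs_against_truth <- function(dmrs, truth) {
  blocks <- truth$blocks
  if (is.null(blocks) || nrow(blocks) == 0) {
    return(list(sensitivity = NA_real_, n_false = nrow(dmrs),
                direction_concordance = NA_real_, n_recovered = 0L,
                n_blocks = 0L))
  }
  overlaps <- function(i, j) {
    blocks$chrom[i] == dmrs$chrom[j] &&
      blocks$start[i] <= dmrs$end[j] && dmrs$start[j] <= blocks$end[i]
  }
  hit_dir <- rep(NA_character_, nrow(blocks))
  dmr_true <- rep(FALSE, nrow(dmrs))
  for (i in seq_len(nrow(blocks))) {
    for (j in seq_len(nrow(dmrs))) {
      if (overlaps(i, j)) {
        hit_dir[i] <- dmrs$direction[j]
        dmr_true[j] <- TRUE
      }
    }
  }
  recovered <- !is.na(hit_dir)
  concord <- ifelse(blocks$sign < 0, "hypo", "hyper")[recovered] ==
    hit_dir[recovered]
  list(sensitivity = mean(recovered),
       n_false = sum(!dmr_true),
       direction_concordance = if (any(recovered)) mean(concord) else NA_real_,
       n_recovered = sum(recovered), n_blocks = nrow(blocks))
}
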
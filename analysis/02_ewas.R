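#!/usr/bin/env Rscript
# Per-cohort EWAS of age: read each cohort back from disk, regress
# methylation on age with the available covariate adjustments (plus the
# consensus-correlation generalized fit for repeated-measures cohorts),
# moderate the variances, and correct for bias and inflation with the
# empirical null. One TSV per cohort.

source("analysis/00_config.R")

beta_files <- list.files(STUDY_DIR, pattern = "_beta\\.tsv$",
                         full.names = TRUE)
dir.create(file.path(OUT, "ewas"), recursive = TRUE, showWarnings = FALSE)

for (bf in beta_files) {
  id <- sub("_beta\\.tsv$", "", basename(bf))
  samples <- read_sample_sheet(file.path(STUDY_DIR,
                                         paste0(id, "_samples.csv")))
  ds <- read_beta_matrix(bf, dataset_id = id, samples = samples)
  ewas <- suppressWarnings(run_ewas(ds, seed = SEED))
  write_ewas_result(ewas, file.path(OUT, "ewas", paste0(id, ".tsv")))
  cat(sprintf(
    "%-10s n=%3d rho=%+.3f bias=%+.3f inflation=%.3f  (%d probes)\n",
    id, ncol(ds$beta), attr(ewas, "rho"), attr(ewas, "mu0"),
    attr(ewas, "sigma0"), nrow(ewas)))
}
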
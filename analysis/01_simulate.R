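#!/usr/bin/env Rscript
# Generate the synthetic multi-cohort methylome study and write it to disk in
# the exchange formats the pipeline consumes (beta TSVs, sample CSVs, BED
# tracks, probe annotation TSV), plus the ground truth for later scoring.

source("analysis/00_config.R")

cfg <- study_config()
toy <- build_toy_annotation(cfg, seed = SEED)
sim <- simulate_multicohort(toy, cfg, seed = SEED)

dir.create(STUDY_DIR, recursive = TRUE, showWarnings = FALSE)

for (d in sim$datasets) {
  write_beta_matrix(d, file.path(STUDY_DIR, paste0(d$dataset_id, "_beta.tsv")))
  write_sample_sheet(d$samples,
                     file.path(STUDY_DIR, paste0(d$dataset_id, "_samples.csv")))
}
write_bed_track(toy$islands, file.path(STUDY_DIR, "cpg_islands.bed"))
write_bed_track(toy$states, file.path(STUDY_DIR, "chromatin_states.bed"))
write_bed_track(toy$tf_sites$ctcf, file.path(STUDY_DIR, "ctcf.bed"))
write_bed_track(toy$tf_sites$ezh2, file.path(STUDY_DIR, "ezh2.bed"))
data.table::fwrite(toy$probes, file.path(STUDY_DIR, "probes.tsv"), sep = "\t")
data.table::fwrite(toy$gene_map, file.path(STUDY_DIR, "gene_map.tsv"),
                   sep = "\t")
data.table::fwrite(
  data.frame(probe_id = sim$truth$probe_id, slope = sim$truth$slope),
  file.path(STUDY_DIR, "truth_slopes.tsv"), sep = "\t")
data.table::fwrite(sim$truth$blocks,
                   file.path(STUDY_DIR, "truth_blocks.tsv"), sep = "\t")

n_samples <- sum(vapply(sim$datasets, function(d) ncol(d$beta), 0L))
cat(sprintf("Simulated %d cohorts, %d samples, %d probes; %d spiked blocks (%d CpGs).\n",
            length(sim$datasets), n_samples, cfg$n_probes,
            nrow(sim$truth$blocks), sum(sim$truth$spiked)))
cat(sprintf("Study written to %s\n", STUDY_DIR))
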
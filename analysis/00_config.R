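# Shared settings for the analysis drivers. Each numbered script can be run
# on its own from the repository root; later steps read the files written by
# earlier ones from results/.

library(metamethyl)

SEED <- 20260919L
OUT <- "results"
STUDY_DIR <- file.path(OUT, "simulated_study")

study_config <- function() {
  # the benchmark study: 10 heterogeneous cohorts, 10,000 probes, 50 spiked
  # age-effect blocks of 3-8 adjacent CpGs at ~0.8% methylation per decade
  sim_config(n_probes = 10000, n_blocks = 50L, dmr_block_len = c(3L, 8L),
             slope_scale = 0.0008, slope_jitter = 0)
}
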
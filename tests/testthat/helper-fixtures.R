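# Shared fixtures, built lazily and memoized so expensive simulations are
# generated at most once per test run.

.fixture_store <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_store[[name]])) .fixture_store[[name]] <- make()
  .fixture_store[[name]]
}

scaled_design <- scaled_cohort_design
clock_design <- clock_cohort_design

toy10k <- function() {
  fixture("toy10k", function() {
    build_toy_annotation(sim_config(n_probes = 10000), seed = 7)
  })
}

# small 5-cohort simulation + full pipeline, shared by several suites
small_sim <- function() {
  fixture("small_sim", function() {
    d <- scaled_design()[c(1, 2, 3, 6, 7), ]
    cfg <- sim_config(cohorts = d, n_probes = 2000, n_blocks = 12L,
                      dmr_block_len = c(3L, 6L), slope_scale = 0.0015,
                      slope_jitter = 0)
    toy <- build_toy_annotation(cfg, seed = 3)
    sim <- simulate_multicohort(toy, cfg, seed = 3)
    pipe <- suppressWarnings(run_age_meta_pipeline(
      sim$datasets, toy$annotation, min_cohorts = 4L, seed = 3))
    list(cfg = cfg, toy = toy, sim = sim, pipe = pipe)
  })
}

# spiked-block benchmark at the full default cohort design (also used by the
# DMR-recovery acceptance check)
benchmark_sim <- function() {
  fixture("benchmark_sim", function() {
    cfg <- sim_config(n_probes = 10000, n_blocks = 50L,
                      dmr_block_len = c(3L, 8L), slope_scale = 0.0008,
                      slope_jitter = 0)
    toy <- build_toy_annotation(cfg, seed = 11)
    sim <- simulate_multicohort(toy, cfg, seed = 11)
    pipe <- suppressWarnings(run_age_meta_pipeline(
      sim$datasets, toy$annotation, seed = 11))
    list(cfg = cfg, toy = toy, sim = sim, pipe = pipe)
  })
}

# minimal hand-built dataset helper
make_dataset <- function(beta, ages, id = "toy", subject = NULL, ...) {
  beta <- as.matrix(beta)
  if (is.null(colnames(beta))) {
    colnames(beta) <- sprintf("s%02d", seq_len(ncol(beta)))
  }
  if (is.null(rownames(beta))) {
    rownames(beta) <- sprintf("cg%04d", seq_len(nrow(beta)))
  }
  samples <- data.frame(
    sample_id = colnames(beta),
    subject_id = subject %||% colnames(beta),
    age = ages, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) samples[[nm]] <- extra[[nm]]
  methylation_dataset(id, beta, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
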
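#!/usr/bin/env Rscript
# Genomic-context enrichment of the called DMRs (chi-square with residual
# decomposition), CpG-bias-corrected gene-set enrichment, overlap with
# simulated transcriptome/proteome DE lists, relationship classification, and
# the candidate-gene report.

source("analysis/00_config.R")

meta <- data.table::fread(file.path(OUT, "meta.tsv"), data.table = FALSE)
cfg <- study_config()
toy <- build_toy_annotation(cfg, seed = SEED)
sim <- simulate_multicohort(toy, cfg, seed = SEED)
dmrs <- call_dmrs(meta, toy$annotation, dmr_config())
dmgs <- define_dmgs(dmrs)
universe <- names(toy$gene_cpg_counts)

enr <- list()
for (cat_name in c("island_context", "chromatin_state", "tf_site")) {
  res <- context_enrichment(dmrs, toy$annotation, cat_name, meta$probe_id)
  enr[[cat_name]] <- data.frame(
    row = rep(rownames(res$table), ncol(res$table)),
    category = rep(colnames(res$table), each = nrow(res$table)),
    observed = as.vector(res$table),
    expected = as.vector(res$expected),
    residual = as.vector(res$residuals))
  cat(sprintf("%-16s chi2 = %8.1f (df %d), p %s 0.005\n", cat_name,
              res$chi2, res$df, if (res$significant) "<" else ">="))
}

# gene sets: random sets plus one set seeded with true differentially
# methylated genes, to show the corrected test finds real signal
gene_sets <- metamethyl:::with_seed(SEED, {
  sets <- lapply(1:20, function(i) sample(universe, 40))
  names(sets) <- sprintf("random_set_%02d", 1:20)
  sets$spiked_set <- unique(c(sample(sim$truth$true_dmgs, 20),
                              sample(universe, 20)))
  sets
})
gs <- geneset_enrichment(dmgs$gene, toy$gene_cpg_counts, gene_sets, universe)
enr$gene_sets <- gs
cat(sprintf("Gene sets: %d/%d significant at FDR<0.005 (spiked set p = %.2g).\n",
            sum(gs$significant), nrow(gs), gs$p[gs$set_id == "spiked_set"]))

# multi-omic overlap with simulated DE lists (63% opposing-sign convention)
dmg_signs <- setNames(ifelse(dmgs$n_hypo >= dmgs$n_hyper, -1, 1), dmgs$gene)
de <- simulate_de_lists(list(true_dmgs = dmgs$gene), universe, odds = 5,
                        n_de = 300, concordance = 0.63,
                        dmg_signs = dmg_signs, seed = SEED)
for (omic in c("mrna", "protein")) {
  ov <- suppressWarnings(omics_overlap(dmgs, de[[omic]]$gene, universe))
  cat(sprintf("%-8s overlap: %.0f%% of DE genes are DMGs (chi2 p = %.2g, OR = %.1f)\n",
              omic, ov$pct_de_in_dmgs, ov$p, ov$odds_ratio))
}
rel <- classify_relationship(dmrs, de$mrna, toy$annotation)
cat(sprintf("Methylation-mRNA relationship negative in %.0f%% of cases.\n",
            attr(rel, "pct_negative")))

candidates <- metamethyl:::with_seed(SEED + 1, {
  c(sample(dmgs$gene, min(5, nrow(dmgs))), sample(universe, 3))
})
report <- candidate_report(candidates, dmgs, de$mrna, de$protein)
print(report, row.names = FALSE)

write_outputs(OUT, enrichments = enr)
data.table::fwrite(report, file.path(OUT, "candidate_report.tsv"), sep = "\t")
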
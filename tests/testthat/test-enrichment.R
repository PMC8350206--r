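test_that("the chi-square kernel matches stats::chisq.test and its residuals", {
  tab <- matrix(c(30, 10, 70, 190), 2, 2)
  res <- pearson_chisq(tab)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  expect_equal(unclass(res$residuals), unclass(ref$residuals),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(res$residuals^2), res$chi2, tolerance = 1e-9)
  # independence-proportional table
  ind <- outer(c(20, 80), c(30, 70)) / 100
  expect_equal(pearson_chisq(ind)$chi2, 0, tolerance = 1e-9)
  # invariance to column permutation
  tab3 <- matrix(c(5, 9, 14, 2, 30, 21), 2, 3)
  expect_equal(pearson_chisq(tab3)$chi2, pearson_chisq(tab3[, 3:1])$chi2,
               tolerance = 1e-12)
})

test_that("context enrichment counts CpGs and detects constructed enrichment", {
  fx <- benchmark_sim()
  ann <- fx$toy$annotation
  dmrs <- fx$pipe$dmrs
  analyzed <- fx$pipe$meta$probe_id
  res <- context_enrichment(dmrs, ann, "island_context", analyzed)
  expect_equal(sum(res$table),
               sum(!is.na(ann$pos[match(analyzed, ann$probe_id)])))
  expect_equal(sum(res$residuals^2), res$chi2, tolerance = 1e-9)
  # spiked blocks sit in probe clusters, i.e. islands: the DMR rows must be
  # island-enriched relative to non-DMR CpGs
  dmr_rows <- rownames(res$table) != "non_dmr"
  expect_gt(sum(res$residuals[dmr_rows, "island"]), 0)
  expect_true(res$significant)
  res_tf <- context_enrichment(dmrs, ann, "tf_site", analyzed)
  expect_true(all(rowSums(res_tf$table) > 0))
})

test_that("rare categories are pooled before testing", {
  set.seed(1)
  tab <- cbind(a = c(500, 400, 4000), b = c(1, 0, 3), c = c(0, 1, 2),
               d = c(300, 200, 2000))
  rownames(tab) <- c("hypo_dmr", "hyper_dmr", "non_dmr")
  merged <- metamethyl:::.merge_rare_columns(tab)
  E <- outer(rowSums(merged), colSums(merged)) / sum(merged)
  expect_true(all(E >= 1) || ncol(merged) == 2)
  expect_equal(sum(merged), sum(tab))
})

test_that("the Wallenius tail reduces to the hypergeometric at odds 1", {
  cases <- list(c(4, 5, 15, 8), c(1, 3, 4, 3), c(10, 60, 540, 150),
                c(0, 5, 5, 4), c(5, 5, 15, 8))
  for (cs in cases) {
    expect_equal(
      wallenius_upper_tail(cs[1], cs[2], cs[3], cs[4], odds = 1),
      phyper(cs[1] - 1, cs[2], cs[3], cs[4], lower.tail = FALSE),
      tolerance = 1e-9)
  }
})

test_that("the Wallenius tail matches brute-force weighted sampling", {
  # exact recursion over sequential weighted draws without replacement
  wallenius_exact <- function(k, m1, m2, n, w) {
    memo <- new.env(parent = emptyenv())
    rec <- function(m1r, m2r, got, left) {
      if (left == 0) return(as.numeric(got >= k))
      key <- paste(m1r, m2r, got, left)
      hit <- memo[[key]]
      if (!is.null(hit)) return(hit)
      tot <- w * m1r + m2r
      p <- 0
      if (m1r > 0) p <- p + w * m1r / tot * rec(m1r - 1, m2r, got + 1, left - 1)
      if (m2r > 0) p <- p + m2r / tot * rec(m1r, m2r - 1, got, left - 1)
      memo[[key]] <- p
      p
    }
    rec(m1, m2, 0, n)
  }
  for (cs in list(list(2, 3, 4, 3, 2), list(1, 3, 4, 3, 0.5),
                  list(4, 6, 8, 7, 3), list(3, 5, 10, 6, 1.7))) {
    expect_equal(
      wallenius_upper_tail(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]]),
      wallenius_exact(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]]),
      tolerance = 1e-9)
  }
})

test_that("gene-set enrichment reduces to hypergeometric when counts are flat", {
  universe <- paste0("G", 1:50)
  counts <- setNames(rep(1L, 50), universe)
  sets <- list(s1 = universe[1:10], s2 = universe[11:40])
  sel <- universe[c(1:6, 45:48)]
  res <- geneset_enrichment(sel, counts, sets, universe)
  expect_equal(res$p[1],
               phyper(sum(sel %in% sets$s1) - 1, 10, 40, 10,
                      lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(res$odds, c(1, 1))
  expect_warning(
    geneset_enrichment(sel, counts, list(bad = "ZZZ"), universe),
    "skipped")
})

test_that("DMG definition keeps per-gene direction profiles", {
  dmrs <- data.frame(direction = c("hypo", "hyper", "hypo"))
  dmrs$genes <- list(c("A"), c("A", "B"), c("C"))
  dmrs$probes <- list("p1", "p2", "p3")
  dmgs <- define_dmgs(dmrs)
  a <- dmgs[dmgs$gene == "A", ]
  expect_equal(a$n_dmrs, 2)
  expect_true(a$mixed)
  expect_identical(dmgs$gene, c("A", "B", "C"))
  expect_false(dmgs$mixed[dmgs$gene == "B"])
  expect_equal(nrow(define_dmgs(dmrs[0, ])), 0)
})

test_that("omics overlap shares the chi-square kernel and reports the odds ratio", {
  universe <- paste0("G", 1:200)
  dmgs <- universe[1:50]
  de <- universe[c(1:30, 101:120)]
  ov <- omics_overlap(dmgs, de, universe)
  tab <- matrix(c(30, 20, 20, 130), 2, 2, byrow = TRUE)
  expect_equal(ov$chi2, pearson_chisq(tab)$chi2, tolerance = 1e-9)
  expect_equal(ov$pct_de_in_dmgs, 100 * 30 / 50)
  expect_equal(ov$odds_ratio, (30 * 130) / (20 * 20), tolerance = 1e-12)
  # Haldane correction engages on empty cells
  ov0 <- omics_overlap(dmgs, universe[1:20], universe)
  expect_true(is.finite(ov0$odds_ratio))
  expect_error(omics_overlap(dmgs, character(0), universe), "degenerate")
  expect_warning(omics_overlap(dmgs, c(de, "NOT_THERE"), universe), "dropped")
})

test_that("methylation-expression relationships classify by opposing signs", {
  ann <- data.frame(probe_id = c("p1", "p2"),
                    chrom = "chr1", pos = c(100, 200),
                    chromatin_state = c("Tx", "Quies"))
  dmrs <- data.frame(chrom = "chr1", start = c(100, 200), end = c(150, 250),
                     direction = c("hypo", "hyper"))
  dmrs$genes <- list("A", "B")
  dmrs$probes <- list("p1", "p2")
  de <- data.frame(gene = c("A", "B"), direction = c(1, 1))
  rel <- classify_relationship(dmrs, de, ann)
  # up-regulated + hypo = negative; up-regulated + hyper = positive
  expect_equal(attr(rel, "pct_negative"), 50)
  expect_identical(sort(rel$stratum), c("active_transcription", "other"))
  expect_equal(rel$negative[rel$stratum == "active_transcription"], 1)
  expect_equal(rel$positive[rel$stratum == "other"], 1)
})

test_that("candidate reports left-join with the field's labels", {
  dmgs <- data.frame(gene = c("FBXO32", "HDAC4"),
                     n_dmrs = c(2L, 19L), n_hypo = c(2L, 10L),
                     n_hyper = c(0L, 9L), mixed = c(FALSE, TRUE))
  rep <- candidate_report(c("FBXO32", "CD36", "HDAC4"), dmgs,
                          de_mrna = data.frame(gene = "HDAC4", direction = 1),
                          de_protein = data.frame(gene = "FBXO32",
                                                  direction = 1))
  expect_identical(rep$methylation,
                   c("Hypomethylation", "", "Hypo and hypermethylation"))
  expect_identical(rep$n_dmrs, c(2L, 0L, 19L))
  expect_identical(rep$mrna[3], "Increased mRNA expression")
  expect_identical(rep$protein[1], "Increased protein expression")
})
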
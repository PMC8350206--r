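test_that("beta matrix TSV round-trips exactly and validates cells", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  beta <- matrix(c(0.1, 0.5, 0.9, 0.2, NA, 0.8), nrow = 3,
                 dimnames = list(c("cgA", "cgB", "cgC"), c("s1", "s2")))
  ds <- methylation_dataset("d1", beta,
                            data.frame(sample_id = c("s1", "s2"),
                                       subject_id = c("u1", "u2"),
                                       age = c(30, 40)))
  write_beta_matrix(ds, tmp)
  back <- read_beta_matrix(tmp, dataset_id = "d1")
  expect_identical(back$beta, beta)

  writeLines(c("probe_id\ts1", "cgA\t1.2"), tmp)
  expect_error(read_beta_matrix(tmp), "cgA")

  writeLines(c("probe_id\ts1", "cgA\t0.5", "cgA\t0.6"), tmp)
  expect_error(read_beta_matrix(tmp), "duplicate probe id: cgA")

  writeLines(c("probe_id\ts1\ts2", "cgA\t0.5\toops"), tmp)
  expect_error(read_beta_matrix(tmp), "row 1.*column 's2'")

  writeLines("probe_id\ts1\ts2", tmp)
  empty <- read_beta_matrix(tmp)
  expect_identical(nrow(empty$beta), 0L)
  expect_identical(ncol(empty$beta), 2L)
})

test_that("sample sheets parse required and optional fields", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,subject_id,age,sex",
               "s1,u1,45.4,M", "s2,u1,45.9,M"), tmp)
  sh <- read_sample_sheet(tmp)
  expect_equal(sh$age[1], 45.4)
  expect_identical(sh$subject_id, c("u1", "u1"))
  expect_true(all(is.na(sh$bmi)))

  writeLines(c("sample_id,subject_id,sex", "s1,u1,M"), tmp)
  expect_error(read_sample_sheet(tmp), "age")

  writeLines(c("sample_id,subject_id,age", "s1,u1,-3"), tmp)
  expect_error(read_sample_sheet(tmp), "non-positive age")
})

test_that("blacklist filtering is a plain, order-preserving set difference", {
  beta <- matrix(runif(5), 5, 1,
                 dimnames = list(paste0("cg", 1:5), "s1"))
  ds <- make_dataset(beta, ages = 33)
  expect_identical(rownames(apply_blacklist(ds, c("cg2", "cg4"))$beta),
                   c("cg1", "cg3", "cg5"))
  expect_identical(apply_blacklist(ds, character(0))$beta, ds$beta)
  expect_identical(nrow(apply_blacklist(ds, paste0("cg", 1:9))$beta), 0L)
})

test_that("BED tracks keep the 0-based half-open convention on disk", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tEnh", tmp)
  tr <- read_bed_track(tmp)
  expect_identical(query_track(tr, "chr1", 150), "Enh")
  expect_identical(query_track(tr, "chr1", 200), "Enh")  # last covered base
  expect_length(query_track(tr, "chr1", 201), 0)
  expect_length(query_track(tr, "chr1", 100), 0)

  out <- withr::local_tempfile(fileext = ".bed")
  write_bed_track(tr, out)
  dt <- read.table(out, sep = "\t")
  expect_identical(as.integer(dt$V2), 100L)
  expect_identical(as.integer(dt$V3), 200L)

  file.create(tmp2 <- withr::local_tempfile(fileext = ".bed"))
  expect_length(read_bed_track(tmp2), 0)
  expect_length(query_track(read_bed_track(tmp2), "chr1", 1), 0)

  writeLines(c("chr1\t100\t200", "chr1\t300\t300"), tmp)
  expect_error(read_bed_track(tmp), "line 2")
})

test_that("island context follows the edge-distance definition", {
  islands <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000))
  probes <- data.frame(
    probe_id = paste0("p", 1:7),
    chrom = "chr1",
    pos = c(1500, 2001, 4000, 4001, 5000, 6001, 12000))
  ann <- annotate_probes(probes, islands, GenomicRanges::GRanges())
  expect_identical(ann$island_context,
                   c("island", "shore", "shore", "shelf", "shelf",
                     "open_sea", "open_sea"))
})

test_that("chromatin states use containment with smallest-start tie-break", {
  states <- GenomicRanges::GRanges(
    c("chr1", "chr1"), IRanges::IRanges(c(500, 1), c(1500, 1000)),
    name = c("B", "A"))
  probes <- data.frame(probe_id = c("p1", "p2", "p3"),
                       chrom = c("chr1", "chr1", "chr9"),
                       pos = c(700, 1400, 50))
  ann <- annotate_probes(probes, GenomicRanges::GRanges(), states)
  expect_identical(ann$chromatin_state, c("A", "B", "Quies"))
  expect_identical(ann$flagged, c(FALSE, FALSE, TRUE))
})

test_that("probes without coordinates keep NA context and are flagged", {
  probes <- data.frame(probe_id = c("p1", "p2"),
                       chrom = c("chr1", NA), pos = c(100, NA))
  ann <- annotate_probes(probes, GenomicRanges::GRanges(),
                         GenomicRanges::GRanges())
  expect_true(is.na(ann$island_context[2]))
  expect_true(ann$flagged[2])
})

test_that("island context partitions every positioned probe exactly once", {
  ann <- toy10k()$annotation
  expect_false(any(is.na(ann$island_context)))
  expect_true(all(ann$island_context %in%
                    c("island", "shore", "shelf", "open_sea")))
})

test_that("regions map to the union of their probes' genes", {
  gene_map <- data.frame(probe_id = c("p1", "p2", "p2"),
                         gene = c("A", "A", "B"))
  probes <- data.frame(probe_id = c("p1", "p2", "p3"),
                       chrom = "chr1", pos = c(100, 200, 5000))
  ann <- annotate_probes(probes, GenomicRanges::GRanges(),
                         GenomicRanges::GRanges(), gene_map = gene_map)
  expect_identical(map_region_to_genes("chr1", 50, 250, ann), c("A", "B"))
  expect_length(map_region_to_genes("chr1", 10000, 11000, ann), 0)
  # enhancer-linked distal gene attaches through the probe, not the locus
  gene_map2 <- rbind(gene_map, data.frame(probe_id = "p3", gene = "ENH"))
  ann2 <- annotate_probes(probes, GenomicRanges::GRanges(),
                          GenomicRanges::GRanges(), gene_map = gene_map2)
  expect_identical(map_region_to_genes("chr1", 4900, 5100, ann2), "ENH")
})

test_that("write_outputs emits the documented files and BED start convention", {
  out <- withr::local_tempdir()
  dmrs <- data.frame(chrom = "chr1", start = 1001, end = 1500, n_cpgs = 3L,
                     mean_b = -0.001, direction = "hypo",
                     fisher_p = 1e-5, stouffer_p = 1e-4, hmfdr = 1e-3,
                     n_hypo_cpgs = 3L, n_hyper_cpgs = 0L)
  dmrs$probes <- list(c("cg1", "cg2", "cg3"))
  dmrs$genes <- list("G1")
  files <- write_outputs(out, dmps = data.frame(probe_id = "cg1", q = 0.001),
                         dmrs = dmrs)
  bed <- read.table(file.path(out, "dmrs.bed"), sep = "\t")
  expect_identical(as.integer(bed$V2), 1000L)  # 1-based start - 1
  expect_identical(as.integer(bed$V3), 1500L)
  expect_equal(bed$V5, round(-log10(1e-4), 3))

  write_outputs(out, dmrs = dmrs[0, ])
  expect_true(file.exists(file.path(out, "dmrs.bed")))
  expect_identical(file.size(file.path(out, "dmrs.bed")), 0)
})
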
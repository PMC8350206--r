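#' Construct a methylation dataset
#'
#' Bundles one cohort's beta matrix (CpG x sample methylation fractions) with
#' its sample sheet and array metadata, validating the core invariants: betas
#' in \[0,1\] (or missing), unique probe ids, and a 1:1 match between matrix
#' columns and sample-sheet rows.
#'
#' @param dataset_id Cohort identifier.
#' @param beta Numeric matrix, probes x samples, rownames = probe ids,
#'   colnames = sample ids, values in \[0,1\] or `NA`.
#' @param samples Data frame of sample records (see [read_sample_sheet()]).
#' @param array_label Free-text array label (e.g. `"EPIC"`, `"450k"`, `"27k"`).
#' @return An object of class `MethylationDataset`.
#' @export
methylation_dataset <- function(dataset_id, beta, samples,
                                array_label = "EPIC") {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta))) {
    if (nrow(beta) > 0) stopf("beta matrix must have probe-id rownames")
    rownames(beta) <- character(0)
  }
  if (anyDuplicated(rownames(beta))) {
    stopf("duplicate probe id: %s", rownames(beta)[duplicated(rownames(beta))][1])
  }
  rng <- suppressWarnings(range(beta, na.rm = TRUE))
  if (nrow(beta) > 0 && ncol(beta) > 0 && !all(is.na(beta)) &&
      (rng[1] < 0 || rng[2] > 1)) {
    bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)[1, ]
    stopf("beta value out of [0,1] at probe '%s', sample '%s'",
          rownames(beta)[bad[1]], colnames(beta)[bad[2]])
  }
  samples <- as.data.frame(samples)
  if (!identical(colnames(beta), samples$sample_id)) {
    if (!setequal(colnames(beta), samples$sample_id) ||
        anyDuplicated(samples$sample_id)) {
      stopf("sample sheet rows do not match beta matrix columns 1:1")
    }
    samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(
    list(dataset_id = dataset_id, beta = beta, samples = samples,
         array_label = array_label),
    class = "MethylationDataset")
}

#' @exportS3Method base::print
print.MethylationDataset <- function(x, ...) {
  cat(sprintf("MethylationDataset '%s' (%s): %d probes x %d samples, %d subjects\n",
              x$dataset_id, x$array_label, nrow(x$beta), ncol(x$beta),
              length(unique(x$samples$subject_id))))
  invisible(x)
}

#' Read a beta matrix from TSV
#'
#' First column = probe ids, remaining columns = one sample each, header row
#' required. Missing cells are preserved as `NA`; values outside \[0,1\] and
#' non-numeric cells are rejected with the offending probe/sample named.
#'
#' @param path TSV file path.
#' @param dataset_id Cohort identifier attached to the result.
#' @param samples Optional sample sheet (data frame); if omitted a minimal one
#'   is derived from the column names (age missing).
#' @param array_label Array label.
#' @return A `MethylationDataset`.
#' @export
read_beta_matrix <- function(path, dataset_id = basename(path),
                             samples = NULL, array_label = "EPIC") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1),
                          data.table = FALSE, na.strings = c("NA", ""))
  probe_ids <- dt[[1]]
  mat <- dt[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    col <- mat[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))[1]
      if (!is.na(bad)) {
        stopf("non-numeric cell at row %d (probe '%s'), column '%s'",
              bad, probe_ids[bad], colnames(mat)[j])
      }
      mat[[j]] <- num
    }
  }
  beta <- as.matrix(mat)
  rownames(beta) <- probe_ids
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(beta),
                          subject_id = colnames(beta),
                          age = NA_real_, stringsAsFactors = FALSE)
  }
  methylation_dataset(dataset_id, beta, samples, array_label)
}

#' Write a beta matrix to TSV
#'
#' @param dataset A `MethylationDataset`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(dataset, path) {
  dt <- data.table::data.table(probe_id = rownames(dataset$beta))
  for (j in colnames(dataset$beta)) dt[[j]] <- dataset$beta[, j]
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

.sample_sheet_cols <- c("sample_id", "subject_id", "age", "sex", "bmi", "t2d",
                        "batch", "time_point", "twin_pair")

#' Read a sample sheet from CSV
#'
#' Requires columns `sample_id`, `subject_id`, `age`; the covariates `sex`,
#' `bmi`, `t2d`, `batch`, `time_point`, `twin_pair` are optional and kept as
#' missing (never imputed) when absent. Repeated measures share `subject_id`.
#'
#' @param path CSV file path.
#' @return A data frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  for (req in c("sample_id", "subject_id", "age")) {
    if (!req %in% colnames(df)) stopf("sample sheet lacks required column '%s'", req)
  }
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df$age <- as.numeric(df$age)
  if (any(!is.na(df$age) & df$age <= 0)) {
    stopf("non-positive age for sample '%s'",
          df$sample_id[which(df$age <= 0)[1]])
  }
  if (any(is.na(df$subject_id) | df$subject_id == "")) {
    stopf("empty subject_id in sample sheet")
  }
  for (opt in setdiff(.sample_sheet_cols, colnames(df))) df[[opt]] <- NA
  df[, .sample_sheet_cols]
}

#' Write a sample sheet to CSV
#' @param samples Data frame of sample records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  data.table::fwrite(samples, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Drop blacklisted probes (e.g. cross-hybridizing) from a dataset
#'
#' @param dataset A `MethylationDataset`.
#' @param blacklist Character vector of probe ids to remove; ids absent from
#'   the dataset are silently ignored.
#' @return The filtered `MethylationDataset`, probe order preserved.
#' @export
apply_blacklist <- function(dataset, blacklist) {
  keep <- !(rownames(dataset$beta) %in% blacklist)
  dataset$beta <- dataset$beta[keep, , drop = FALSE]
  dataset
}

#' Read a BED track into a GRanges
#'
#' BED intervals are 0-based half-open on disk and converted to the 1-based
#' closed convention of [GenomicRanges::GRanges] in memory. An optional fourth
#' column is kept as the interval name (e.g. a chromatin-state label).
#'
#' @param path BED file path.
#' @param label Track label stored in `metadata()$label`.
#' @return A `GRanges` with a `name` metadata column.
#' @export
read_bed_track <- function(path, label = basename(path)) {
  dt <- if (file.size(path) == 0) {
    data.frame()
  } else {
    data.table::fread(path, header = FALSE, data.table = FALSE, fill = TRUE)
  }
  if (nrow(dt) == 0 || ncol(dt) < 3) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$label <- label
    return(gr)
  }
  bad <- which(dt[[2]] >= dt[[3]])
  if (length(bad) > 0) {
    stopf("BED interval with start >= end at line %d of %s", bad[1], path)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = dt[[1]],
    ranges = IRanges::IRanges(start = dt[[2]] + 1L, end = dt[[3]]),
    name = if (ncol(dt) >= 4) as.character(dt[[4]]) else NA_character_)
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Write a GRanges to BED (0-based half-open)
#' @param gr A `GRanges`; the `name` metadata column becomes BED column 4 and
#'   an optional `score` column becomes BED column 5 (strand written as ".").
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(gr, path) {
  if (length(gr) == 0) {
    file.create(path)
    return(invisible(path))
  }
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% colnames(mc)) {
    dt$name <- as.character(mc$name)
    if ("score" %in% colnames(mc)) {
      dt$score <- mc$score
      dt$strand <- "."
    }
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Query the labels of intervals containing a genomic position
#'
#' @param track `GRanges` track (see [read_bed_track()]).
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @return Character vector of interval names covering the position (possibly
#'   empty).
#' @export
query_track <- function(track, chrom, pos) {
  if (length(track) == 0) return(character(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, track)
  as.character(track$name[S4Vectors::subjectHits(hits)])
}

#' Annotate probes with CpG-island context, chromatin state, TF binding and genes
#'
#' Island context is computed from the distance in bp between the probe
#' position and the nearest island edge: 0 (inside) = `island`, (0, 2 kb\] =
#' `shore`, (2 kb, 4 kb\] = `shelf`, > 4 kb = `open_sea`. The chromatin state
#' is the state interval containing the position; when several overlap, the
#' interval with the smallest start wins. Probes on chromosomes absent from
#' the state track fall back to `"Quies"` and are flagged. Probes with missing
#' coordinates keep `NA` context and are likewise flagged (they stay usable
#' for position-level statistics but are excluded from regional analyses).
#'
#' @param probes Data frame with columns `probe_id`, `chrom`, `pos` (1-based).
#' @param islands `GRanges` of CpG islands.
#' @param states `GRanges` of chromatin-state intervals (labels in `name`).
#' @param tf_sites Named list of `GRanges`, typically `list(ctcf=, ezh2=)`.
#' @param gene_map Data frame `probe_id`, `gene` (multiple rows per probe
#'   allowed; includes enhancer-linked genes).
#' @return A `ProbeAnnotation` data frame: `probe_id`, `chrom`, `pos`,
#'   `island_context`, `chromatin_state`, `ctcf`, `ezh2`, `genes`
#'   (list-column), `flagged`.
#' @export
annotate_probes <- function(probes, islands, states,
                            tf_sites = list(), gene_map = NULL) {
  ann <- data.frame(probe_id = as.character(probes$probe_id),
                    chrom = as.character(probes$chrom),
                    pos = as.numeric(probes$pos),
                    stringsAsFactors = FALSE)
  positioned <- !is.na(ann$chrom) & !is.na(ann$pos)
  if (any(positioned & ann$pos <= 0)) stopf("probe positions must be positive")
  gr <- GenomicRanges::GRanges(
    ann$chrom[positioned],
    IRanges::IRanges(ann$pos[positioned], ann$pos[positioned]))

  # island context from edge distance
  ctx <- rep(NA_character_, nrow(ann))
  if (length(islands) > 0 && any(positioned)) {
    same_chr <- as.character(GenomicRanges::seqnames(gr)) %in%
      as.character(GenomicRanges::seqnames(islands))
    d <- rep(NA_real_, length(gr))
    hit <- GenomicRanges::distanceToNearest(gr, islands)
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    # GRanges distance counts the gap (adjacent ranges have distance 0), so
    # the bp distance to the island edge is gap + 1 for non-overlapping probes
    edge_dist <- ifelse(IRanges::overlapsAny(gr, islands), 0,
                        ifelse(is.na(d), Inf, d + 1))
    edge_dist[!same_chr] <- Inf
    ctx[positioned] <- cut(edge_dist,
                           breaks = c(-1, 0, 2000, 4000, Inf),
                           labels = c("island", "shore", "shelf", "open_sea")) |>
      as.character()
  } else if (any(positioned)) {
    ctx[positioned] <- "open_sea"
  }
  ann$island_context <- ctx

  # chromatin state; tie-break = smallest interval start
  state <- rep(NA_character_, nrow(ann))
  state_missing <- rep(FALSE, nrow(ann))
  if (any(positioned)) {
    st <- rep(NA_character_, length(gr))
    if (length(states) > 0) {
      hits <- GenomicRanges::findOverlaps(gr, states)
      if (length(hits) > 0) {
        hdf <- data.frame(q = S4Vectors::queryHits(hits),
                          s = S4Vectors::subjectHits(hits))
        hdf$start <- GenomicRanges::start(states)[hdf$s]
        hdf <- hdf[order(hdf$q, hdf$start, hdf$s), ]
        hdf <- hdf[!duplicated(hdf$q), ]
        st[hdf$q] <- as.character(states$name[hdf$s])
      }
    }
    miss <- is.na(st)
    st[miss] <- "Quies"
    state[positioned] <- st
    state_missing[positioned] <- miss
  }
  ann$chromatin_state <- state

  for (tf in c("ctcf", "ezh2")) {
    flag <- rep(NA, nrow(ann))
    track <- tf_sites[[tf]]
    flag[positioned] <- if (!is.null(track) && length(track) > 0) {
      IRanges::overlapsAny(gr, track)
    } else FALSE
    ann[[tf]] <- flag
  }

  genes <- rep(list(character(0)), nrow(ann))
  if (!is.null(gene_map) && nrow(gene_map) > 0) {
    sp <- split(as.character(gene_map$gene), as.character(gene_map$probe_id))
    idx <- match(ann$probe_id, names(sp))
    genes[!is.na(idx)] <- lapply(sp[idx[!is.na(idx)]], unique)
  }
  ann$genes <- genes
  ann$flagged <- !positioned | state_missing
  ann
}

#' Map a genomic region to the genes of its member probes
#'
#' Returns the union of the gene sets (gene body, promoter and enhancer-linked
#' alike) of all probes falling inside the region.
#'
#' @param chrom Chromosome.
#' @param start,end 1-based closed region bounds.
#' @param annotation `ProbeAnnotation` data frame from [annotate_probes()].
#' @return Character vector of gene symbols (possibly empty).
#' @export
map_region_to_genes <- function(chrom, start, end, annotation) {
  inside <- !is.na(annotation$chrom) & annotation$chrom == chrom &
    !is.na(annotation$pos) & annotation$pos >= start & annotation$pos <= end
  sort(unique(unlist(annotation$genes[inside])))
}

#' Write pipeline outputs to a directory
#'
#' Writes the DMP table (CSV), the DMR table (TSV) and its BED companion
#' (score = -log10 Stouffer p, strand "."), one TSV per enrichment table, and
#' the clock model as a single JSON document.
#'
#' @param out_dir Output directory (created if needed).
#' @param dmps Optional data frame of per-CpG meta-analysis results.
#' @param dmrs Optional DMR data frame (see [call_dmrs()]).
#' @param enrichments Optional named list of data frames.
#' @param clock_model Optional `ClockModel` (see [train_clock()]).
#' @return Invisible character vector of files written.
#' @export
write_outputs <- function(out_dir, dmps = NULL, dmrs = NULL,
                          enrichments = NULL, clock_model = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(dmps)) {
    f <- file.path(out_dir, "dmps.csv")
    data.table::fwrite(dmps, f, na = "NA", quote = FALSE)
    written <- c(written, f)
  }
  if (!is.null(dmrs)) {
    f <- file.path(out_dir, "dmrs.tsv")
    flat <- dmrs
    flat$probes <- vapply(dmrs$probes, paste, "", collapse = ";")
    data.table::fwrite(flat, f, sep = "\t", na = "NA", quote = FALSE)
    bed <- file.path(out_dir, "dmrs.bed")
    if (nrow(dmrs) > 0) {
      gr <- GenomicRanges::GRanges(
        dmrs$chrom, IRanges::IRanges(dmrs$start, dmrs$end),
        name = sprintf("DMR_%d_%s", seq_len(nrow(dmrs)), dmrs$direction),
        score = round(-log10(pmax(dmrs$stouffer_p, 1e-300)), 3))
      write_bed_track(gr, bed)
    } else {
      file.create(bed)
    }
    written <- c(written, f, bed)
  }
  for (nm in names(enrichments)) {
    f <- file.path(out_dir, sprintf("enrichment_%s.tsv", nm))
    data.table::fwrite(as.data.frame(enrichments[[nm]]), f, sep = "\t",
                       na = "NA", quote = FALSE)
    written <- c(written, f)
  }
  if (!is.null(clock_model)) {
    f <- file.path(out_dir, "clock_model.json")
    write_clock_model(clock_model, f)
    written <- c(written, f)
  }
  invisible(written)
}
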
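#' Default cohort design table for the synthetic multi-cohort generator
#'
#' Ten cohorts loosely mirroring the heterogeneity of published skeletal-muscle
#' methylome studies: sample sizes from ~20 to ~280, cohort-specific age
#' windows inside 18-89 years, a majority-male mix, two smaller cohorts on
#' legacy low-coverage arrays, repeated measures (multiple time points per
#' subject) in the exercise-intervention cohorts, and diabetes cases in three
#' cohorts. Coverage fractions stand in for the relative probe content of the
#' EPIC-, 450k- and 27k-like designs on the toy probe universe.
#'
#' @return A data frame with one row per cohort.
#' @export
default_cohort_design <- function() {
  data.frame(
    dataset_id = sprintf("cohort%02d", 1:10),
    array_label = c("EPIC", "EPIC", "450k", "EPIC", "EPIC",
                    "27k", "450k", "EPIC", "EPIC", "27k"),
    n_subjects = c(282L, 66L, 65L, 21L, 24L, 51L, 48L, 14L, 8L, 22L),
    samples_per_subject = c(1L, 3L, 1L, 3L, 2L, 1L, 1L, 3L, 5L, 1L),
    age_min = c(20, 18, 23, 20, 23, 21, 18, 20, 19, 53),
    age_max = c(77, 45, 61, 39, 58, 77, 89, 71, 39, 80),
    age_mean = c(59.4, 32, 44, 26, 38.9, 50, 47, 45.4, 29, 68),
    age_sd = c(7.9, 8.1, 8.2, 5.9, 10, 17, 26, 22.3, 6, 8),
    pct_male = c(0.54, 0.80, 0, 1, 1, 1, 1, 1, 1, 0.45),
    has_t2d = c(TRUE, FALSE, TRUE, FALSE, FALSE,
                FALSE, FALSE, FALSE, FALSE, TRUE),
    n_batches = c(2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    coverage = c(0.95, 0.95, 0.55, 0.95, 0.95, 0.12, 0.55, 0.95, 0.95, 0.12),
    stringsAsFactors = FALSE)
}

#' Reduced-size variant of the default cohort design
#'
#' The same 10-cohort structure (arrays, age windows, repeated measures, T2D
#' cohorts) at roughly one-seventh of the sample sizes, for replicated
#' simulation studies where the full design would be needlessly slow.
#'
#' @return A data frame with one row per cohort.
#' @export
scaled_cohort_design <- function() {
  d <- default_cohort_design()
  d$n_subjects <- c(40L, 20L, 20L, 10L, 10L, 15L, 15L, 8L, 6L, 10L)
  d$samples_per_subject <- c(1L, 2L, 1L, 2L, 1L, 1L, 1L, 2L, 2L, 1L)
  d
}

#' Cohort design for the epigenetic-clock benchmark
#'
#' Eight cross-sectional EPIC-like cohorts with wide, overlapping age ranges
#' and full probe coverage — the setting in which a leave-one-dataset-out
#' clock evaluation is informative.
#'
#' @return A data frame with one row per cohort.
#' @export
clock_cohort_design <- function() {
  data.frame(
    dataset_id = sprintf("clock%02d", 1:8), array_label = "EPIC",
    n_subjects = c(30L, 26L, 24L, 28L, 22L, 24L, 26L, 22L),
    samples_per_subject = 1L,
    age_min = c(18, 20, 25, 18, 30, 20, 18, 22),
    age_max = c(89, 75, 80, 70, 85, 78, 82, 69),
    age_mean = c(48, 42, 50, 40, 55, 45, 47, 44),
    age_sd = c(22, 16, 18, 15, 17, 16, 20, 14),
    pct_male = 0.71, has_t2d = FALSE, n_batches = 1L, coverage = 1.0,
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Defines the study conditions the generator emulates. Effects are generated
#' on the latent logistic scale; `slope_scale` is nevertheless expressed as a
#' methylation-fraction change per year at the probe's baseline (0.0008/year,
#' i.e. ~0.8% per decade, the magnitude typical of age effects on the muscle
#' methylome) and converted internally via the delta method.
#'
#' @param cohorts Cohort design data frame (see [default_cohort_design()]);
#'   may contain fewer/more rows to change the number of cohorts.
#' @param n_probes Number of probes in the toy universe.
#' @param frac_age_cpgs Fraction of probes carrying a true age effect (spiked
#'   in adjacent blocks); ignored when `n_blocks` is given.
#' @param n_blocks Exact number of spiked blocks (overrides `frac_age_cpgs`).
#' @param dmr_block_len Integer range (min, max) of adjacent CpGs per spiked
#'   block.
#' @param slope_scale True methylation-fraction change per year at spiked
#'   probes (sign assigned per block).
#' @param slope_jitter Relative jitter of per-probe slopes around
#'   `slope_scale` (uniform in `1 +/- slope_jitter`).
#' @param hypo_fraction Fraction of spiked blocks losing methylation with age
#'   (defaults to the slight hypomethylation excess typical of ageing muscle).
#' @param noise_sd Residual sd on the latent logit scale.
#' @param batch_sd,subject_sd Sd of per-probe batch and subject random effects
#'   (latent scale).
#' @param confounding Age-BMI confounding: expected BMI increase (kg/m^2) per
#'   10 years of age.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(cohorts = default_cohort_design(),
                       n_probes = 10000L,
                       frac_age_cpgs = 0.05,
                       n_blocks = NULL,
                       dmr_block_len = c(2L, 10L),
                       slope_scale = 0.0008,
                       slope_jitter = 0.25,
                       hypo_fraction = 0.57,
                       noise_sd = 0.15,
                       batch_sd = 0.05,
                       subject_sd = 0.08,
                       confounding = 0) {
  stopifnot(n_probes >= 1, frac_age_cpgs >= 0, frac_age_cpgs <= 1,
            slope_scale >= 0, all(cohorts$coverage > 0),
            all(cohorts$coverage <= 1),
            dmr_block_len[1] >= 1, dmr_block_len[2] >= dmr_block_len[1])
  if (any(cohorts$samples_per_subject < 1)) {
    stopf("samples_per_subject must be >= 1")
  }
  structure(list(
    cohorts = cohorts, n_probes = as.integer(n_probes),
    frac_age_cpgs = frac_age_cpgs, n_blocks = n_blocks,
    dmr_block_len = as.integer(dmr_block_len),
    slope_scale = slope_scale, slope_jitter = slope_jitter,
    hypo_fraction = hypo_fraction, noise_sd = noise_sd,
    batch_sd = batch_sd, subject_sd = subject_sd,
    confounding = confounding), class = "SimulationConfig")
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- out < lo | out > hi
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(out, lo), hi)
}

#' Generate a toy genome annotation
#'
#' Lays `n_probes` on two toy chromosomes with a realistic spacing mixture
#' (CpG-island clusters of 5-15 probes 50-200 bp apart; background probes
#' 2-20 kb apart), derives island intervals from the clusters, tiles
#' chromatin states (quiescent-dominated alphabet), scatters CTCF sites and
#' places EZH2 sites preferentially over islands, and assigns probes to genes
#' with skewed CpG counts (1-60) so that CpG-count bias in gene-set enrichment
#' is exercised. A small fraction of probes also gets an enhancer-linked distal
#' gene.
#'
#' @param config A `SimulationConfig`.
#' @param seed Integer seed; fixed seed gives identical annotation.
#' @return A list with elements `probes` (data frame `probe_id`, `chrom`,
#'   `pos`), `islands`, `states`, `tf_sites` (`GRanges`), `gene_map`
#'   (probe-gene pairs), `gene_cpg_counts`, and `annotation` (the
#'   [annotate_probes()] table).
#' @export
build_toy_annotation <- function(config, seed = 1L) {
  with_seed(substream_seed(seed, "annotation"), {
    n <- config$n_probes
    n1 <- ceiling(n / 2)
    lay <- function(n_chr, chrom) {
      pos <- numeric(0)
      isl <- NULL
      cursor <- 50000
      while (length(pos) < n_chr) {
        if (runif(1) < 0.10) {
          # island cluster with shore/shelf satellites on the 3' side
          k <- sample(4:12, 1)
          p <- cursor + cumsum(c(0, round(runif(k - 1, 50, 200))))
          isl <- rbind(isl, c(p[1] - 100, p[k] + 100))
          pos <- c(pos, p)
          edge <- p[k] + 100
          if (runif(1) < 0.9) {
            pos <- c(pos, edge + sort(round(runif(sample(2:4, 1), 100, 1900))))
          }
          if (runif(1) < 0.5) {
            pos <- c(pos, edge + sort(round(runif(sample(1:2, 1), 2100, 3900))))
          }
          cursor <- max(pos) + round(runif(1, 5000, 20000))
        } else {
          pos <- c(pos, cursor)
          cursor <- cursor + round(runif(1, 2000, 20000))
        }
      }
      pos <- sort(pos[seq_len(n_chr)])
      isl <- isl[isl[, 1] <= max(pos), , drop = FALSE]
      list(pos = pos, islands = isl, chrom = chrom)
    }
    chr1 <- lay(n1, "chr1")
    chr2 <- lay(n - n1, "chr2")
    probes <- data.frame(
      probe_id = sprintf("cg%07d", seq_len(n)),
      chrom = c(rep("chr1", n1), rep("chr2", n - n1)),
      pos = c(chr1$pos, chr2$pos),
      stringsAsFactors = FALSE)
    islands <- GenomicRanges::GRanges(
      c(rep("chr1", nrow(chr1$islands)), rep("chr2", nrow(chr2$islands))),
      IRanges::IRanges(c(chr1$islands[, 1], chr2$islands[, 1]),
                       c(chr1$islands[, 2], chr2$islands[, 2])))

    # chromatin states: quiescent-dominated tiling
    state_alphabet <- c("TssA", "TssFlnk", "Tx", "TxWk", "EnhG", "Enh",
                        "TssBiv", "EnhBiv", "ReprPC", "Het", "Quies")
    state_w <- c(0.05, 0.04, 0.08, 0.12, 0.04, 0.08,
                 0.02, 0.02, 0.05, 0.10, 0.40)
    tile_states <- function(chrom, upto) {
      starts <- ends <- numeric(0)
      labs <- character(0)
      cursor <- 1
      while (cursor < upto) {
        len <- round(runif(1, 2000, 30000))
        starts <- c(starts, cursor)
        ends <- c(ends, min(cursor + len - 1, upto))
        labs <- c(labs, sample(state_alphabet, 1, prob = state_w))
        cursor <- cursor + len
      }
      GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends), name = labs)
    }
    states <- suppressWarnings(c(tile_states("chr1", max(chr1$pos) + 10000),
                                 tile_states("chr2", max(chr2$pos) + 10000)))

    # CTCF anchored on ~3% of probes (plus flanks); EZH2 preferentially
    # over islands
    n_ctcf <- max(1, round(n * 0.03))
    anchor <- sample(n, n_ctcf)
    ctcf <- GenomicRanges::reduce(GenomicRanges::GRanges(
      probes$chrom[anchor],
      IRanges::IRanges(pmax(1, probes$pos[anchor] - round(runif(n_ctcf, 50, 400))),
                       probes$pos[anchor] + round(runif(n_ctcf, 50, 400)))))
    isl_pick <- sort(sample(length(islands), max(1, round(length(islands) * 0.3))))
    ezh2 <- suppressWarnings(c(islands[isl_pick],
              GenomicRanges::GRanges(
                sample(c("chr1", "chr2"), max(1, round(n / 200)), replace = TRUE),
                IRanges::IRanges(
                  round(runif(max(1, round(n / 200)), 1, max(chr2$pos))),
                  width = 500))))

    # genes: consecutive probe runs with skewed CpG counts, 1-60 per gene
    sizes_pool <- 1:60
    size_w <- 1 / sizes_pool
    gene_map <- NULL
    gid <- 0
    for (chrom in c("chr1", "chr2")) {
      idx <- which(probes$chrom == chrom)
      i <- 1
      while (i <= length(idx)) {
        gid <- gid + 1
        sz <- sample(sizes_pool, 1, prob = size_w)
        take <- idx[i:min(i + sz - 1, length(idx))]
        gene_map <- rbind(gene_map, data.frame(
          probe_id = probes$probe_id[take],
          gene = sprintf("GENE%04d", gid), stringsAsFactors = FALSE))
        i <- i + sz
      }
    }
    # enhancer-linked distal genes for ~2% of probes
    genes_all <- unique(gene_map$gene)
    n_enh <- max(1, round(n * 0.02))
    enh_probes <- sample(probes$probe_id, n_enh)
    gene_map <- rbind(gene_map, data.frame(
      probe_id = enh_probes,
      gene = sample(genes_all, n_enh, replace = TRUE),
      stringsAsFactors = FALSE))
    gene_map <- unique(gene_map)

    ann <- annotate_probes(probes, islands, states,
                           tf_sites = list(ctcf = ctcf, ezh2 = ezh2),
                           gene_map = gene_map)
    counts <- table(gene_map$gene)
    list(probes = probes, islands = islands, states = states,
         tf_sites = list(ctcf = ctcf, ezh2 = ezh2),
         gene_map = gene_map,
         gene_cpg_counts = setNames(as.integer(counts), names(counts)),
         annotation = ann)
  })
}

#' Draw the per-probe ground truth (baselines, slopes, spiked blocks)
#' @keywords internal
.draw_truth <- function(toy, config, seed) {
  with_seed(substream_seed(seed, "truth"), {
    probes <- toy$probes
    n <- nrow(probes)
    ann <- toy$annotation
    # bimodal baselines tied to island context (islands mostly unmethylated)
    ctx <- ann$island_context
    alpha <- numeric(n)
    is_island <- !is.na(ctx) & ctx == "island"
    is_shore <- !is.na(ctx) & ctx == "shore"
    alpha[is_island] <- rnorm(sum(is_island), -2.5, 0.8)
    alpha[is_shore] <- rnorm(sum(is_shore), -0.5, 1.5)
    rest <- !(is_island | is_shore)
    hi <- runif(sum(rest)) < 0.75
    alpha[rest][hi] <- rnorm(sum(hi), 2.2, 0.7)
    alpha[rest][!hi] <- rnorm(sum(!hi), 0, 1)

    # candidate runs of adjacent probes (gap <= 500 bp) for spiked blocks
    ord <- order(probes$chrom, probes$pos)
    runs <- list()
    run <- ord[1]
    for (k in seq_along(ord)[-1]) {
      i <- ord[k]; j <- ord[k - 1]
      if (probes$chrom[i] == probes$chrom[j] &&
          probes$pos[i] - probes$pos[j] <= 500) {
        run <- c(run, i)
      } else {
        runs[[length(runs) + 1]] <- run
        run <- i
      }
    }
    runs[[length(runs) + 1]] <- run
    runs <- runs[vapply(runs, length, 1L) >= config$dmr_block_len[1]]

    target_cpgs <- if (!is.null(config$n_blocks)) Inf else
      round(config$frac_age_cpgs * n)
    n_blocks_target <- config$n_blocks %||% Inf
    runs <- runs[sample(length(runs))]
    slope <- numeric(n)
    blocks <- NULL
    spiked_cpgs <- 0
    bid <- 0
    for (r in runs) {
      if (bid >= n_blocks_target || spiked_cpgs >= target_cpgs) break
      len <- sample(seq(config$dmr_block_len[1],
                        min(config$dmr_block_len[2], length(r))), 1)
      start_at <- sample(length(r) - len + 1, 1)
      memb <- r[start_at:(start_at + len - 1)]
      sgn <- if (runif(1) < config$hypo_fraction) -1 else 1
      mag <- config$slope_scale *
        runif(len, 1 - config$slope_jitter, 1 + config$slope_jitter)
      slope[memb] <- sgn * mag
      bid <- bid + 1
      blocks <- rbind(blocks, data.frame(
        block_id = bid, chrom = probes$chrom[memb[1]],
        start = min(probes$pos[memb]), end = max(probes$pos[memb]),
        sign = sgn, n_cpgs = len, stringsAsFactors = FALSE))
      spiked_cpgs <- spiked_cpgs + len
    }

    # latent-scale slopes via delta method at the baseline
    p0 <- plogis(alpha)
    slope_latent <- slope / pmax(p0 * (1 - p0), 0.02)

    # sparse covariate effects (adjusted for downstream, so null-safe)
    g_sex <- ifelse(runif(n) < 0.05, rnorm(n, 0, 0.3), 0)
    g_bmi <- ifelse(runif(n) < 0.05, rnorm(n, 0, 0.02), 0)
    g_t2d <- ifelse(runif(n) < 0.02, rnorm(n, 0, 0.2), 0)
    g_time <- ifelse(runif(n) < 0.02, rnorm(n, 0, 0.1), 0)

    dmg <- character(0)
    if (!is.null(blocks)) {
      spiked_idx <- which(slope != 0)
      dmg <- sort(unique(unlist(ann$genes[spiked_idx])))
    }
    list(probe_id = probes$probe_id, alpha = alpha, slope = slope,
         slope_latent = slope_latent, spiked = slope != 0,
         blocks = blocks %||% data.frame(), g_sex = g_sex, g_bmi = g_bmi,
         g_t2d = g_t2d, g_time = g_time, true_dmgs = dmg)
  })
}

#' Simulate a multi-cohort methylation study
#'
#' For each cohort in the design, draws subjects (ages from a truncated normal
#' inside the cohort's window, sex, BMI with optional age confounding, T2D
#' status, batches, time points), assays a random probe subset of size
#' `coverage * n_probes`, and emits betas from the latent-logistic model
#' `y = alpha_g + beta_g (age - 50) + gamma_g' covariates + u_subject +
#' b_batch + eps`, squashed through the inverse logit and clipped to
#' (0.001, 0.999). Spiked blocks share the sign of their age slope. Cohort
#' streams are seeded by hashing `(dataset_id, seed)` so results do not depend
#' on iteration order.
#'
#' @param toy Output of [build_toy_annotation()].
#' @param config A `SimulationConfig`.
#' @param seed Integer seed.
#' @return A list with `datasets` (list of `MethylationDataset`) and `truth`
#'   (per-probe slopes, spiked blocks, true DMGs).
#' @export
simulate_multicohort <- function(toy, config, seed = 1L) {
  truth <- .draw_truth(toy, config, seed)
  probes <- toy$probes
  n <- nrow(probes)
  datasets <- vector("list", nrow(config$cohorts))
  names(datasets) <- config$cohorts$dataset_id
  for (ci in seq_len(nrow(config$cohorts))) {
    ch <- config$cohorts[ci, ]
    datasets[[ci]] <- with_seed(substream_seed(seed, ch$dataset_id), {
      ns <- ch$n_subjects
      reps <- ch$samples_per_subject
      S <- ns * reps
      age0 <- .rtruncnorm(ns, ch$age_mean, ch$age_sd, ch$age_min, ch$age_max)
      sex <- ifelse(runif(ns) < ch$pct_male, "M", "F")
      bmi <- 25 + config$confounding / 10 * (age0 - 50) + rnorm(ns, 0, 3.5)
      t2d <- if (ch$has_t2d) as.integer(runif(ns) < 0.3) else rep(0L, ns)
      subj_idx <- rep(seq_len(ns), each = reps)
      tp <- if (reps > 1) rep(seq_len(reps), times = ns) else rep(1L, ns)
      batch <- sample(seq_len(ch$n_batches), ns, replace = TRUE)[subj_idx]
      samples <- data.frame(
        sample_id = sprintf("%s_s%03d_t%d", ch$dataset_id, subj_idx, tp),
        subject_id = sprintf("%s_s%03d", ch$dataset_id, subj_idx),
        age = age0[subj_idx], sex = sex[subj_idx], bmi = bmi[subj_idx],
        t2d = t2d[subj_idx], batch = paste0("b", batch),
        time_point = paste0("t", tp),
        twin_pair = NA_character_, stringsAsFactors = FALSE)

      assayed <- sort(sample(n, round(ch$coverage * n)))
      G <- length(assayed)
      sex01 <- as.numeric(sex == "M")[subj_idx]
      post <- as.numeric(tp > 1)
      u_subj <- matrix(rnorm(G * ns, 0, config$subject_sd), G, ns)
      b_batch <- matrix(rnorm(G * ch$n_batches, 0, config$batch_sd),
                        G, ch$n_batches)
      y <- matrix(truth$alpha[assayed], G, S) +
        truth$slope_latent[assayed] %o% (samples$age - 50) +
        truth$g_sex[assayed] %o% sex01 +
        truth$g_bmi[assayed] %o% (samples$bmi - 25) +
        truth$g_t2d[assayed] %o% as.numeric(samples$t2d) +
        truth$g_time[assayed] %o% post +
        u_subj[, subj_idx] + b_batch[, batch] +
        matrix(rnorm(G * S, 0, config$noise_sd), G, S)
      beta <- pmin(pmax(plogis(y), 0.001), 0.999)
      rownames(beta) <- probes$probe_id[assayed]
      colnames(beta) <- samples$sample_id
      methylation_dataset(ch$dataset_id, beta, samples, ch$array_label)
    })
  }
  list(datasets = datasets, truth = truth)
}

#' Simulate mRNA and protein differential-expression gene lists
#'
#' DE genes are drawn without replacement with probability proportional to
#' `odds` for true differentially methylated genes (DMGs) and 1 otherwise.
#' For selected genes that are true DMGs, the expression direction opposes the
#' gene's methylation sign with probability `concordance` (the "negative
#' relationship" of methylation-expression integration); other genes get a
#' random sign.
#'
#' @param truth Truth object from [simulate_multicohort()] (uses `true_dmgs`
#'   and block signs via `dmg_signs` when available).
#' @param universe Character vector of all genes.
#' @param odds Enrichment odds of DMGs among DE genes (>= 1).
#' @param n_de Number of DE genes per list.
#' @param concordance Probability that a DE DMG's expression sign opposes its
#'   methylation sign.
#' @param dmg_signs Optional named vector of methylation signs per DMG
#'   (defaults to -1, hypomethylation, for all true DMGs).
#' @param seed Integer seed.
#' @return List with data frames `mrna` and `protein` (`gene`, `direction`).
#' @export
simulate_de_lists <- function(truth, universe, odds = 1, n_de = 500,
                              concordance = 0.63, dmg_signs = NULL,
                              seed = 1L) {
  stopifnot(odds >= 1)
  if (n_de > length(universe)) stopf("n_de exceeds the gene universe")
  is_dmg <- universe %in% truth$true_dmgs
  if (is.null(dmg_signs)) {
    dmg_signs <- setNames(rep(-1, length(truth$true_dmgs)), truth$true_dmgs)
  }
  draw <- function(sub_seed) {
    with_seed(sub_seed, {
      if (n_de == 0) {
        return(data.frame(gene = character(0), direction = numeric(0)))
      }
      w <- ifelse(is_dmg, odds, 1)
      genes <- sample(universe, n_de, prob = w)
      meth_sign <- dmg_signs[genes]
      dir <- ifelse(
        !is.na(meth_sign) & runif(n_de) < concordance,
        -meth_sign,
        ifelse(!is.na(meth_sign), meth_sign, sample(c(-1, 1), n_de, TRUE)))
      data.frame(gene = genes, direction = as.numeric(dir),
                 stringsAsFactors = FALSE)
    })
  }
  list(mrna = draw(substream_seed(seed, "mrna")),
       protein = draw(substream_seed(seed, "protein")))
}
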
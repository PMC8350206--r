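#' DMR-calling configuration
#'
#' @param lambda Bandwidth in bp: CpGs further apart than this are never
#'   merged, and the Gaussian kernel sd is `lambda / C` (default 1000/2 =
#'   500 bp).
#' @param C Kernel scaling factor.
#' @param fdr_cpg Per-CpG threshold on the BH-corrected smoothed p-values.
#' @param min_cpgs Minimum CpGs per region (a 1-CpG "region" is just a DMP).
#' @param fisher,stouffer,hmfdr Region-level significance thresholds; an
#'   emitted DMR must pass all three.
#' @return A `DmrConfig` list.
#' @export
dmr_config <- function(lambda = 1000, C = 2, fdr_cpg = 0.005,
                       min_cpgs = 2L, fisher = 0.005, stouffer = 0.005,
                       hmfdr = 0.005) {
  stopifnot(lambda > 0, C > 0)
  list(lambda = lambda, C = C, sigma = lambda / C, fdr_cpg = fdr_cpg,
       min_cpgs = as.integer(min_cpgs),
       thresholds = c(fisher = fisher, stouffer = stouffer, hmfdr = hmfdr))
}

#' Gaussian-kernel smoothing of squared z-scores with Satterthwaite p-values
#'
#' For CpGs sorted by position within a chromosome, computes the normalized
#' kernel average `S_i = sum_j K_ij z_j^2 / sum_j K_ij` with
#' `K_ij = exp(-(x_i - x_j)^2 / (2 sigma^2))`, truncated at `3 sigma`
#' (`K_ii = 1` always). Under the null each `z^2` is chi-square with 1 df, so
#' `E[S] = 1` and the two-moment (Satterthwaite) match gives effective df
#' `nu_i = (sum K)^2 / sum K^2` and `p_i = P(chisq_nu > nu S)`. Smoothing
#' never crosses chromosomes.
#'
#' @param chrom,pos Probe coordinates (1-based positions).
#' @param z Per-CpG (meta-analysis) z-scores.
#' @param config A `DmrConfig`.
#' @return Data frame `chrom`, `pos`, `z`, `S`, `nu`, `p_smooth`, in position
#'   order within chromosome.
#' @export
smooth_statistics <- function(chrom, pos, z, config = dmr_config()) {
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; z <- z[ord]
  sigma <- config$sigma
  win <- 3 * sigma
  n <- length(pos)
  S <- nu <- numeric(n)
  z2 <- z^2
  lo <- 1L; hi <- 1L
  for (i in seq_len(n)) {
    while (lo < i && (chrom[lo] != chrom[i] || pos[i] - pos[lo] > win)) {
      lo <- lo + 1L
    }
    if (hi < i) hi <- i
    while (hi < n && chrom[hi + 1L] == chrom[i] &&
           pos[hi + 1L] - pos[i] <= win) {
      hi <- hi + 1L
    }
    j <- lo:hi
    K <- exp(-(pos[j] - pos[i])^2 / (2 * sigma^2))
    sk <- sum(K)
    S[i] <- sum(K * z2[j]) / sk
    nu[i] <- sk^2 / sum(K^2)
  }
  data.frame(chrom = chrom, pos = pos, z = z, S = S, nu = nu,
             p_smooth = pchisq(nu * S, df = nu, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Aggregate significant smoothed CpGs into candidate regions
#'
#' CpGs whose BH-corrected smoothed p-value falls below `fdr_cpg` are grouped
#' greedily along each chromosome; a gap larger than `lambda` bp starts a new
#' region, and regions with fewer than `min_cpgs` members are discarded.
#'
#' @param smoothed Output of [smooth_statistics()] (must carry a `probe_id`
#'   column if member ids are wanted downstream).
#' @param config A `DmrConfig`.
#' @return Data frame of candidate regions with a `members` list-column of row
#'   indices into `smoothed`.
#' @export
call_candidate_regions <- function(smoothed, config = dmr_config()) {
  fdr <- bh_fdr(smoothed$p_smooth)
  sig <- which(!is.na(fdr) & fdr < config$fdr_cpg)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_cpgs = integer(0))
  if (length(sig) == 0) {
    empty$members <- list()
    return(empty)
  }
  sig <- sig[order(smoothed$chrom[sig], smoothed$pos[sig])]
  chrom <- smoothed$chrom[sig]
  pos <- smoothed$pos[sig]
  new_region <- c(TRUE, chrom[-1] != chrom[-length(sig)] |
                    diff(pos) > config$lambda)
  grp <- cumsum(new_region)
  out <- do.call(rbind, lapply(split(seq_along(sig), grp), function(ii) {
    data.frame(chrom = chrom[ii[1]], start = pos[ii[1]],
               end = pos[ii[length(ii)]], n_cpgs = length(ii))
  }))
  out$members <- unname(split(sig, grp))
  out <- out[out$n_cpgs >= config$min_cpgs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region-level combination statistics
#'
#' Fisher: `X = -2 sum log p` referred to chi-square with `2m` df. Stouffer:
#' `z_S = sum z / sqrt(m)` (signed meta z-scores), two-sided p. HMFDR: the
#' harmonic mean `m / sum(1/q)` of the member FDRs. The region effect is the
#' inverse-variance-weighted mean of member effects; direction is `hypo` when
#' it is negative, `hyper` otherwise.
#'
#' @param p,q,z,b,se Member per-CpG meta-analysis p-values, FDRs, z-scores,
#'   effects and standard errors.
#' @return List `fisher_p`, `stouffer_p`, `hmfdr`, `mean_b`, `direction`.
#' @export
region_statistics <- function(p, q, z, b, se = NULL) {
  m <- length(p)
  stopifnot(m >= 1)
  p <- pmax(p, .Machine$double.xmin)
  fisher_p <- pchisq(-2 * sum(log(p)), df = 2 * m, lower.tail = FALSE)
  z_s <- sum(z) / sqrt(m)
  stouffer_p <- 2 * pnorm(-abs(z_s))
  hmfdr <- m / sum(1 / pmax(q, .Machine$double.xmin))
  w <- if (is.null(se)) rep(1, m) else 1 / se^2
  mean_b <- sum(w * b) / sum(w)
  list(fisher_p = fisher_p, stouffer_p = stouffer_p, hmfdr = hmfdr,
       mean_b = mean_b, direction = if (mean_b < 0) "hypo" else "hyper")
}

#' Call differentially methylated regions from meta-analysis results
#'
#' Joins the meta-analysis table with probe coordinates (probes without
#' coordinates are excluded from regional analysis), smooths the squared meta
#' z-scores, aggregates significant CpGs into candidate regions, computes the
#' three region statistics, BH-adjusts the Fisher p across candidates, and
#' emits regions passing all three thresholds, annotated with genes and
#' sorted by position.
#'
#' @param meta A `MetaResult` data frame.
#' @param annotation `ProbeAnnotation` from [annotate_probes()].
#' @param config A `DmrConfig`.
#' @return A DMR data frame: `chrom`, `start`, `end` (1-based closed, probe
#'   positions), `n_cpgs`, `probes` (list), `mean_b`, `direction`,
#'   `fisher_p` (BH-adjusted), `stouffer_p`, `hmfdr`, `n_hypo_cpgs`,
#'   `n_hyper_cpgs`, `genes` (list).
#' @export
call_dmrs <- function(meta, annotation, config = dmr_config()) {
  idx <- match(meta$probe_id, annotation$probe_id)
  keep <- !is.na(idx) & !is.na(annotation$chrom[idx]) &
    !is.na(annotation$pos[idx]) & is.finite(meta$z_meta)
  df <- data.frame(
    probe_id = meta$probe_id[keep],
    chrom = annotation$chrom[idx[keep]],
    pos = annotation$pos[idx[keep]],
    z = meta$z_meta[keep], p = meta$p_meta[keep], q = meta$q_meta[keep],
    b = meta$b_meta[keep], se = meta$se_meta[keep],
    stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  sm <- smooth_statistics(df$chrom, df$pos, df$z, config)
  cand <- call_candidate_regions(sm, config)
  empty <- data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    n_cpgs = integer(0), mean_b = numeric(0), direction = character(0),
    fisher_p = numeric(0), stouffer_p = numeric(0), hmfdr = numeric(0),
    n_hypo_cpgs = integer(0), n_hyper_cpgs = integer(0))
  if (nrow(cand) == 0) {
    empty$probes <- list(); empty$genes <- list()
    return(empty)
  }
  stats <- lapply(cand$members, function(ii) {
    region_statistics(df$p[ii], df$q[ii], df$z[ii], df$b[ii], df$se[ii])
  })
  cand$mean_b <- vapply(stats, `[[`, 0, "mean_b")
  cand$direction <- vapply(stats, `[[`, "", "direction")
  cand$fisher_p <- bh_fdr(vapply(stats, `[[`, 0, "fisher_p"))
  cand$stouffer_p <- vapply(stats, `[[`, 0, "stouffer_p")
  cand$hmfdr <- vapply(stats, `[[`, 0, "hmfdr")
  cand$n_hypo_cpgs <- vapply(cand$members, function(ii) sum(df$b[ii] < 0), 0L)
  cand$n_hyper_cpgs <- vapply(cand$members, function(ii) sum(df$b[ii] >= 0), 0L)
  th <- config$thresholds
  pass <- cand$fisher_p < th["fisher"] & cand$stouffer_p < th["stouffer"] &
    cand$hmfdr < th["hmfdr"]
  out <- cand[pass, , drop = FALSE]
  out$probes <- lapply(out$members, function(ii) df$probe_id[ii])
  out$genes <- lapply(seq_len(nrow(out)), function(i) {
    map_region_to_genes(out$chrom[i], out$start[i], out$end[i], annotation)
  })
  out$members <- NULL
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
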
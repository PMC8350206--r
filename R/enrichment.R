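#' Pearson chi-square test on a contingency table, with residuals
#'
#' The shared kernel behind every enrichment and overlap test in the package:
#' expected counts from the margins, `chi2 = sum (O - E)^2 / E`, df =
#' `(r-1)(c-1)`, and the per-cell Pearson residuals `(O - E)/sqrt(E)` whose
#' squares sum to the statistic.
#'
#' @param tab Numeric matrix of observed counts.
#' @return A `ContingencyResult` list: `table`, `expected`, `chi2`, `df`,
#'   `p`, `residuals`.
#' @export
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n == 0 || nrow(tab) < 2 || ncol(tab) < 2) {
    stopf("contingency table needs >= 2 rows and columns with positive total")
  }
  E <- outer(rowSums(tab), colSums(tab)) / n
  if (any(E == 0)) stopf("margin with zero total in contingency table")
  resid <- (tab - E) / sqrt(E)
  chi2 <- sum(resid^2)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(table = tab, expected = E, chi2 = chi2, df = df,
       p = pchisq(chi2, df, lower.tail = FALSE), residuals = resid)
}

.merge_rare_columns <- function(tab, min_expected = 1) {
  repeat {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    bad <- which(apply(E, 2, min) < min_expected)
    if (length(bad) == 0 || ncol(tab) <= 2) return(tab)
    if (!"other" %in% colnames(tab)) {
      worst <- bad[which.min(apply(E, 2, min)[bad])]
      colnames(tab)[worst] <- "other"
      next
    }
    other <- which(colnames(tab) == "other")
    donor <- setdiff(bad, other)
    if (length(donor) == 0) {
      # "other" itself is still too small: absorb the smallest column
      donor <- setdiff(order(colSums(tab)), other)[1]
    } else {
      donor <- donor[which.min(apply(E, 2, min)[donor])]
    }
    tab[, other] <- tab[, other] + tab[, donor]
    tab <- tab[, -donor, drop = FALSE]
  }
}

#' Genomic-context enrichment of DMR CpGs
#'
#' Compares, at the CpG level, the distribution of probes inside
#' hypomethylated DMRs, hypermethylated DMRs, and all remaining analyzed
#' probes (non-DMR) across the levels of a genomic-context category:
#' CpG-island context, chromatin state, or TF binding (CTCF/EZH2). Categories
#' whose expected count falls below 1 are pooled into `"other"` before
#' testing.
#'
#' @param dmrs DMR data frame from [call_dmrs()].
#' @param annotation `ProbeAnnotation` data frame.
#' @param category One of `"island_context"`, `"chromatin_state"`,
#'   `"tf_site"`.
#' @param analyzed_probes Character vector of all probes in the meta-analysis
#'   universe (defines the non-DMR row).
#' @return A `ContingencyResult` (see [pearson_chisq()]) with a `significant`
#'   flag at p < 0.005.
#' @export
context_enrichment <- function(dmrs, annotation,
                               category = c("island_context",
                                            "chromatin_state", "tf_site"),
                               analyzed_probes) {
  category <- match.arg(category)
  ann <- annotation[match(analyzed_probes, annotation$probe_id), ]
  ann <- ann[!is.na(ann$probe_id) & !is.na(ann$pos), ]
  lev <- switch(category,
    island_context = ann$island_context,
    chromatin_state = ann$chromatin_state,
    tf_site = ifelse(ann$ctcf & ann$ezh2, "ctcf+ezh2",
                     ifelse(ann$ctcf, "ctcf",
                            ifelse(ann$ezh2, "ezh2", "none"))))
  hypo <- unlist(dmrs$probes[dmrs$direction == "hypo"])
  hyper <- unlist(dmrs$probes[dmrs$direction == "hyper"])
  grp <- ifelse(ann$probe_id %in% hypo, "hypo_dmr",
                ifelse(ann$probe_id %in% hyper, "hyper_dmr", "non_dmr"))
  tab <- table(factor(grp, levels = c("hypo_dmr", "hyper_dmr", "non_dmr")),
               lev)
  tab <- unclass(tab)[rowSums(unclass(tab)) > 0, , drop = FALSE]
  tab <- .merge_rare_columns(tab)
  res <- pearson_chisq(tab)
  res$category <- category
  res$significant <- res$p < 0.005
  res
}

#' Upper tail of the Wallenius noncentral hypergeometric distribution
#'
#' Probability of drawing at least `k` of the `m1` "special" items when `n`
#' items are taken from an urn of `m1 + m2` without replacement, each special
#' item weighted `odds` relative to the others. Computed from the integral
#' representation of the pmf; with `odds = 1` it reduces exactly to the
#' central hypergeometric tail.
#'
#' @param k Observed overlap.
#' @param m1 Special items in the urn (genes in the set).
#' @param m2 Other items.
#' @param n Number drawn (selected genes).
#' @param odds Weight ratio (> 0).
#' @return `P(X >= k)`.
#' @export
wallenius_upper_tail <- function(k, m1, m2, n, odds = 1) {
  stopifnot(odds > 0, n <= m1 + m2)
  support <- max(0, n - m2):min(n, m1)
  if (k <= min(support)) return(1)
  if (k > max(support)) return(0)
  # pmf via the integral representation, after substituting u = t^(1/D):
  # pmf(j) = C(m1,j) C(m2,n-j) D Int_0^1 u^(D-1) (1-u)^(n-j) (1-u^w)^j du.
  # The integrand is normalized by its peak before quadrature so that large
  # problems neither overflow nor underflow.
  pmf1 <- function(j) {
    D <- odds * (m1 - j) + (m2 - (n - j))
    if (D <= 0) return(0)
    lc <- lchoose(m1, j) + lchoose(m2, n - j) + log(D)
    lf <- function(u) {
      out <- rep(-Inf, length(u))
      pos <- u > 0 & u < 1
      up <- u[pos]
      a <- (D - 1) * log(up) + (n - j) * log1p(-up)
      if (j > 0) a <- a + j * log1p(-up^odds)
      out[pos] <- a
      out
    }
    pk <- optimize(lf, c(0, 1), maximum = TRUE)
    M <- pk$objective
    if (!is.finite(M)) return(0)
    val <- integrate(function(u) exp(lf(u) - M), 0, 1,
                     rel.tol = 1e-11, subdivisions = 1000L)$value
    exp(lc + M) * val
  }
  upper <- support[support >= k]
  lower <- support[support < k]
  # sum the smaller tail for accuracy
  if (length(upper) <= length(lower)) {
    min(1, sum(vapply(upper, pmf1, 0)))
  } else {
    max(0, min(1, 1 - sum(vapply(lower, pmf1, 0))))
  }
}

#' CpG-count-bias-corrected gene-set enrichment of DMR genes
#'
#' Genes with more CpGs have more opportunity to harbour a DMR, so a plain
#' hypergeometric test over-rejects. Each set is tested with a Wallenius
#' noncentral hypergeometric upper tail whose odds parameter is the ratio of
#' the mean per-gene CpG count inside vs outside the set — the empirical
#' selection-weight bias the set carries. FDR is BH across sets; FDR < 0.005
#' is flagged significant.
#'
#' @param dmr_genes Character vector of selected (differentially methylated)
#'   genes.
#' @param gene_cpg_counts Named integer vector: analyzed CpGs per gene.
#' @param gene_sets Named list of character vectors.
#' @param universe Genes with at least one analyzed CpG.
#' @return A `GeneSetResult` data frame: `set_id`, `n_set`, `n_selected`,
#'   `n_overlap`, `odds`, `p`, `fdr`, `significant`.
#' @export
geneset_enrichment <- function(dmr_genes, gene_cpg_counts, gene_sets,
                               universe) {
  universe <- unique(universe)
  sel <- intersect(dmr_genes, universe)
  w <- gene_cpg_counts[universe]
  w[is.na(w)] <- 1
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(gene_sets[[id]], universe)
    if (length(set) == 0) {
      warnf("gene set '%s' does not intersect the universe; skipped", id)
      return(NULL)
    }
    in_set <- universe %in% set
    odds <- mean(w[in_set]) / mean(w[!in_set])
    k <- sum(sel %in% set)
    p <- wallenius_upper_tail(k, m1 = length(set),
                              m2 = length(universe) - length(set),
                              n = length(sel), odds = odds)
    data.frame(set_id = id, n_set = length(set), n_selected = length(sel),
               n_overlap = k, odds = odds, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set_id = character(0), n_set = integer(0),
                      n_selected = integer(0), n_overlap = integer(0),
                      odds = numeric(0), p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  }
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$fdr < 0.005
  rownames(out) <- NULL
  out
}

#' Define differentially methylated genes (DMGs) from called DMRs
#'
#' Every gene with at least one DMR annotated to it is a DMG; the per-gene
#' direction profile (number of hypo- and hyper-methylated DMRs) is kept,
#' since a minority of genes harbour both.
#'
#' @param dmrs DMR data frame from [call_dmrs()].
#' @return Data frame `gene`, `n_dmrs`, `n_hypo`, `n_hyper`, `mixed`.
#' @export
define_dmgs <- function(dmrs) {
  if (nrow(dmrs) == 0) {
    return(data.frame(gene = character(0), n_dmrs = integer(0),
                      n_hypo = integer(0), n_hyper = integer(0),
                      mixed = logical(0)))
  }
  pairs <- do.call(rbind, lapply(seq_len(nrow(dmrs)), function(i) {
    g <- dmrs$genes[[i]]
    if (length(g) == 0) return(NULL)
    data.frame(gene = g, hypo = dmrs$direction[i] == "hypo",
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) {
    return(define_dmgs(dmrs[0, , drop = FALSE]))
  }
  agg <- do.call(rbind, lapply(split(pairs$hypo, pairs$gene), function(h) {
    data.frame(n_dmrs = length(h), n_hypo = sum(h), n_hyper = sum(!h))
  }))
  out <- data.frame(gene = rownames(agg), agg, stringsAsFactors = FALSE)
  out$mixed <- out$n_hypo > 0 & out$n_hyper > 0
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Overlap of DMGs with a differential-expression gene list
#'
#' 2x2 chi-square (shared [pearson_chisq()] kernel) of DMG status against DE
#' status over an explicit gene universe, with the odds ratio
#' (Haldane-corrected when a cell is empty) and the percentage of DE genes
#' that are also DMGs.
#'
#' @param dmgs Character vector of DMG symbols (or the data frame from
#'   [define_dmgs()]).
#' @param de_genes Character vector of DE genes; genes outside the universe
#'   are dropped with a warning.
#' @param universe All genes eligible for both calls.
#' @return An `OverlapResult` list: `table`, `chi2`, `df`, `p`, `odds_ratio`,
#'   `pct_de_in_dmgs`, `significant`.
#' @export
omics_overlap <- function(dmgs, de_genes, universe) {
  if (is.data.frame(dmgs)) dmgs <- dmgs$gene
  universe <- unique(universe)
  outside <- setdiff(de_genes, universe)
  if (length(outside) > 0) {
    warnf("%d DE genes outside the universe dropped", length(outside))
    de_genes <- intersect(de_genes, universe)
  }
  is_dmg <- universe %in% dmgs
  is_de <- universe %in% de_genes
  tab <- table(factor(is_dmg, c(TRUE, FALSE), c("DMG", "non_DMG")),
               factor(is_de, c(TRUE, FALSE), c("DE", "non_DE")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("degenerate 2x2 overlap table (empty margin)")
  }
  res <- pearson_chisq(unclass(tab))
  o <- unclass(tab)
  if (any(o == 0)) o <- o + 0.5  # Haldane correction
  res$odds_ratio <- (o[1, 1] * o[2, 2]) / (o[1, 2] * o[2, 1])
  res$pct_de_in_dmgs <- 100 * tab["DMG", "DE"] / sum(tab[, "DE"])
  res$significant <- res$p < 0.005
  res
}

#' Classify methylation-expression relationships per gene
#'
#' A "negative relationship" means the signs oppose: a gene up-regulated with
#' age whose DMR loses methylation, or vice versa. Mixed-profile genes are
#' classified per DMR (each DMR votes). Votes are stratified by whether the
#' DMR lies in a chromatin state of active transcription, where the positive
#' pattern is biologically expected.
#'
#' @param dmrs DMR data frame from [call_dmrs()].
#' @param de_list Data frame `gene`, `direction` (+1/-1) of expression change.
#' @param active_states Chromatin-state labels counted as active
#'   transcription.
#' @param annotation `ProbeAnnotation` (to look up the member probes' states).
#' @return Data frame of vote counts and percentages by relationship and
#'   stratum, plus attribute `pct_negative` (overall).
#' @export
classify_relationship <- function(dmrs, de_list, annotation,
                                  active_states = c("Tx", "TxWk")) {
  if (nrow(dmrs) == 0 || nrow(de_list) == 0) {
    out <- data.frame(stratum = character(0), negative = integer(0),
                      positive = integer(0), pct_negative = numeric(0))
    attr(out, "pct_negative") <- NA_real_
    return(out)
  }
  de_dir <- setNames(de_list$direction, de_list$gene)
  votes <- do.call(rbind, lapply(seq_len(nrow(dmrs)), function(i) {
    genes <- intersect(dmrs$genes[[i]], de_list$gene)
    if (length(genes) == 0) return(NULL)
    st <- annotation$chromatin_state[match(dmrs$probes[[i]],
                                           annotation$probe_id)]
    active <- mean(st %in% active_states, na.rm = TRUE) > 0.5
    meth_sign <- if (dmrs$direction[i] == "hypo") -1 else 1
    data.frame(stratum = if (active) "active_transcription" else "other",
               negative = meth_sign * de_dir[genes] < 0,
               stringsAsFactors = FALSE)
  }))
  if (is.null(votes)) {
    return(classify_relationship(dmrs[0, , drop = FALSE], de_list[0, , drop = FALSE],
                                 annotation, active_states))
  }
  out <- do.call(rbind, lapply(split(votes$negative, votes$stratum),
                               function(v) {
    data.frame(negative = sum(v), positive = sum(!v),
               pct_negative = 100 * mean(v))
  }))
  out <- data.frame(stratum = rownames(out), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "pct_negative") <- 100 * mean(votes$negative)
  out
}

#' Candidate-gene multi-omic report
#'
#' Left-joins a candidate gene list against the DMG table and the DE lists:
#' genes with no DMR are reported with a count of 0 and a blank methylation
#' direction; direction labels are "Hypomethylation", "Hypermethylation" or
#' "Hypo and hypermethylation".
#'
#' @param genes Character vector of candidate gene symbols.
#' @param dmgs Data frame from [define_dmgs()].
#' @param de_mrna,de_protein Optional DE data frames (`gene`, `direction`).
#' @return Data frame `gene`, `n_dmrs`, `methylation`, `mrna`, `protein`.
#' @export
candidate_report <- function(genes, dmgs, de_mrna = NULL, de_protein = NULL) {
  idx <- match(genes, dmgs$gene)
  n_dmrs <- ifelse(is.na(idx), 0L, dmgs$n_dmrs[idx])
  meth <- rep("", length(genes))
  hit <- !is.na(idx)
  meth[hit] <- ifelse(
    dmgs$mixed[idx[hit]], "Hypo and hypermethylation",
    ifelse(dmgs$n_hypo[idx[hit]] > 0, "Hypomethylation", "Hypermethylation"))
  lab <- function(de, what) {
    if (is.null(de)) return(rep("", length(genes)))
    d <- de$direction[match(genes, de$gene)]
    ifelse(is.na(d), "",
           ifelse(d > 0, sprintf("Increased %s expression", what),
                  sprintf("Decreased %s expression", what)))
  }
  data.frame(gene = genes, n_dmrs = n_dmrs, methylation = meth,
             mrna = lab(de_mrna, "mRNA"), protein = lab(de_protein, "protein"),
             stringsAsFactors = FALSE)
}
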
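#' Build the per-cohort design matrix for the age EWAS
#'
#' Age is always the first modelled covariate; the requested adjustment
#' covariates are kept only when present in the sample sheet, not entirely
#' missing, and non-constant. Dropped covariates are reported via a warning so
#' cohort-specific designs (e.g. all-male cohorts) are visible in logs.
#'
#' @param samples Sample sheet data frame.
#' @param covariates Character vector of adjustment covariate names.
#' @return A list with `design` (model matrix), `keep` (logical vector of
#'   retained samples) and `used` (covariates retained).
#' @export
build_design <- function(samples, covariates = c("sex", "bmi", "t2d",
                                                 "batch", "time_point")) {
  if (all(is.na(samples$age))) stopf("age is missing for every sample")
  usable <- character(0)
  for (cv in covariates) {
    v <- samples[[cv]]
    if (is.null(v) || all(is.na(v))) {
      warnf("covariate '%s' absent or all-missing; dropped", cv)
    } else if (length(unique(v[!is.na(v)])) < 2) {
      warnf("covariate '%s' constant in cohort; dropped", cv)
    } else {
      usable <- c(usable, cv)
    }
  }
  df <- samples[, c("age", usable), drop = FALSE]
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (length(unique(df$age)) < 2) stopf("age is constant in this cohort")
  design <- model.matrix(
    ~ ., data = df[, c("age", usable), drop = FALSE])
  # drop aliased columns, keeping age estimable
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    drop_cols <- qr_d$pivot[-seq_len(qr_d$rank)]
    if (any(colnames(design)[drop_cols] == "age")) {
      stopf("age is confounded with the adjustment covariates")
    }
    warnf("design rank-deficient; dropping columns: %s",
          paste(colnames(design)[drop_cols], collapse = ", "))
    design <- design[, -drop_cols, drop = FALSE]
  }
  list(design = design, keep = keep, used = usable)
}

#' Per-probe covariate-adjusted linear models of methylation on age
#'
#' Ordinary least squares of the beta value against age plus adjustment
#' covariates, probe by probe (complete-case per probe), via
#' [limma::lmFit()]. When `rho` and a subject blocking vector are supplied the
#' fit is generalized least squares under the exchangeable within-subject
#' correlation model (limma's `block`/`correlation` machinery), which is how
#' repeated measures enter the EWAS.
#'
#' @param dataset A `MethylationDataset`.
#' @param covariates Adjustment covariates (see [build_design()]).
#' @param rho Optional consensus within-subject correlation (from
#'   [estimate_consensus_correlation()]).
#' @return A data frame with columns `probe_id`, `b` (methylation fraction
#'   per year), `stdev_unscaled`, `se_raw`, `s2`, `df`, `degenerate`; the
#'   design is attached as attribute `design`.
#' @export
fit_age_models <- function(dataset, covariates = c("sex", "bmi", "t2d",
                                                   "batch", "time_point"),
                           rho = NULL) {
  d <- build_design(dataset$samples, covariates)
  beta <- dataset$beta[, d$keep, drop = FALSE]
  if (nrow(beta) == 0) stopf("dataset has no probes")
  if (!is.null(rho) && abs(rho) > 1e-12) {
    fit <- limma::lmFit(beta, d$design,
                        block = dataset$samples$subject_id[d$keep],
                        correlation = rho)
  } else {
    fit <- limma::lmFit(beta, d$design)
  }
  res <- data.frame(
    probe_id = rownames(beta),
    b = fit$coefficients[, "age"],
    stdev_unscaled = fit$stdev.unscaled[, "age"],
    s2 = fit$sigma^2,
    df = fit$df.residual,
    stringsAsFactors = FALSE)
  res$se_raw <- res$stdev_unscaled * fit$sigma
  res$degenerate <- !is.finite(res$s2) | res$s2 < 1e-14 | res$df < 1 |
    !is.finite(res$b)
  rownames(res) <- NULL
  attr(res, "design") <- d$design
  attr(res, "rho") <- if (is.null(rho)) 0 else rho
  res
}

#' Consensus within-subject correlation for repeated-measures cohorts
#'
#' Estimates, on a probe subsample, the within-subject correlation of
#' methylation residuals and combines the per-probe estimates into a single
#' consensus value on the Fisher-z scale with a 15% trimmed mean — the
#' `duplicateCorrelation` construction of limma, which is called directly.
#' Cohorts without repeated measures return 0, making the subsequent
#' generalized fit identical to ordinary least squares.
#'
#' @param dataset A `MethylationDataset`.
#' @param covariates Adjustment covariates.
#' @param max_probes Probe subsample cap (evenly spaced, deterministic);
#'   all probes are used when fewer are available.
#' @return The consensus correlation (scalar in (-1, 1)).
#' @export
estimate_consensus_correlation <- function(dataset,
                                           covariates = c("sex", "bmi", "t2d",
                                                          "batch",
                                                          "time_point"),
                                           max_probes = 600L) {
  subj <- dataset$samples$subject_id
  if (!any(duplicated(subj))) return(0)
  d <- suppressWarnings(build_design(dataset$samples, covariates))
  beta <- dataset$beta[, d$keep, drop = FALSE]
  G <- nrow(beta)
  idx <- if (G > max_probes) {
    unique(round(seq(1, G, length.out = max_probes)))
  } else {
    seq_len(G)
  }
  dc <- suppressWarnings(limma::duplicateCorrelation(
    beta[idx, , drop = FALSE], d$design, block = subj[d$keep]))
  rho <- dc$consensus.correlation
  if (!is.finite(rho)) 0 else rho
}

#' Empirical-Bayes variance moderation of per-probe residual variances
#'
#' Shrinks each probe's residual variance toward a common prior using the
#' method-of-moments fit of a scaled inverse-chi-square prior on the observed
#' variances (limma's `squeezeVar`, i.e. matching digamma/trigamma moments of
#' log s^2), then forms the moderated t statistic with `d0 + d` degrees of
#' freedom. Degenerate probes (zero residual variance or no residual df) get
#' missing statistics and never enter the prior fit.
#'
#' @param fit Data frame from [fit_age_models()].
#' @return The input with columns `s2_post`, `t`, `df_total`, `p_raw` added;
#'   prior df `d0` and prior variance `s02` attached as attributes.
#' @export
moderate_statistics <- function(fit) {
  ok <- !fit$degenerate
  if (sum(ok) < 2) stopf("need at least 2 non-degenerate probes to moderate")
  sq <- tryCatch(
    limma::squeezeVar(fit$s2[ok], fit$df[ok]),
    error = function(e) {
      warnf("variance-prior fit failed (%s); using infinite prior df",
            conditionMessage(e))
      list(df.prior = Inf, var.prior = mean(fit$s2[ok]),
           var.post = rep(mean(fit$s2[ok]), sum(ok)))
    })
  d0 <- sq$df.prior
  fit$s2_post <- NA_real_
  fit$s2_post[ok] <- sq$var.post
  fit$t <- fit$b / (fit$stdev_unscaled * sqrt(fit$s2_post))
  fit$df_total <- ifelse(ok, pmin(fit$df + d0, 1e6), NA_real_)
  fit$p_raw <- 2 * pt(-abs(fit$t), df = fit$df_total)
  fit$p_raw[!ok] <- NA_real_
  fit$t[!ok] <- NA_real_
  attr(fit, "d0") <- d0
  attr(fit, "s02") <- sq$var.prior
  fit
}

#' Probit-transformed signed z-scores from two-sided p-values
#'
#' `z = sign(t) * qnorm(p/2, lower = FALSE)`, the scale on which the
#' empirical-null model is fitted.
#'
#' @param p Two-sided p-values.
#' @param sign_stat Statistic carrying the sign (e.g. moderated t).
#' @return Numeric vector of signed z-scores.
#' @export
probit_z <- function(p, sign_stat) {
  p <- pmax(p, 1e-300)
  sign(sign_stat) * qnorm(p / 2, lower.tail = FALSE)
}

#' Run one cohort's full EWAS of age
#'
#' Fits the per-probe models (with the consensus-correlation generalized fit
#' when the cohort has repeated measures), moderates the variances, converts
#' the moderated p-values to signed probit z-scores, estimates the empirical
#' null (bias `mu0`, inflation `sigma0`) and returns bias/inflation-corrected
#' statistics. Both the p-values and the effect uncertainties are rescaled
#' (`se_corr = se * sigma0`) so the meta-analysis uses corrected weights.
#'
#' @param dataset A `MethylationDataset`.
#' @param covariates Adjustment covariates.
#' @param correct_null Apply the empirical-null correction (default TRUE).
#' @param seed Seed for the empirical-null EM restarts.
#' @return An `EwasResult` data frame (`probe_id`, `b`, `se`, `t`, `df_total`,
#'   `p_raw`, `z_raw`, `z_corr`, `p_corr`, `se_corr`) with dataset-level
#'   attributes `dataset_id`, `d0`, `s02`, `rho`, `mu0`, `sigma0`, `pi0`.
#' @export
run_ewas <- function(dataset, covariates = c("sex", "bmi", "t2d",
                                             "batch", "time_point"),
                     correct_null = TRUE, seed = 1L) {
  rho <- estimate_consensus_correlation(dataset, covariates)
  fit <- fit_age_models(dataset, covariates, rho = if (rho != 0) rho else NULL)
  fit <- moderate_statistics(fit)
  fit$se <- fit$stdev_unscaled * sqrt(fit$s2_post)
  fit$z_raw <- probit_z(fit$p_raw, fit$t)
  if (correct_null) {
    en <- estimate_empirical_null(fit$z_raw[is.finite(fit$z_raw)], seed = seed)
  } else {
    en <- list(mu0 = 0, sigma0 = 1, pi0 = 1, method = "none")
  }
  corr <- apply_empirical_null(fit$z_raw, en$mu0, en$sigma0)
  fit$z_corr <- corr$z
  fit$p_corr <- corr$p
  # corrected se defined so that b / se_corr reproduces the corrected z on
  # the effect scale (the moderated statistic is t-distributed, so this also
  # absorbs the t-to-normal quantile map, keeping the normal-theory
  # meta-analysis calibrated for small cohorts); the b = z = 0 limit falls
  # back to the plain inflation rescale
  se_fallback <- fit$se * en$sigma0
  fit$se_corr <- ifelse(
    is.finite(fit$z_corr) & abs(fit$z_corr) > 1e-12 & abs(fit$b) > 0,
    abs(fit$b / fit$z_corr), se_fallback)
  structure(fit, dataset_id = dataset$dataset_id,
            rho = rho, mu0 = en$mu0, sigma0 = en$sigma0, pi0 = en$pi0,
            d0 = attr(fit, "d0"), s02 = attr(fit, "s02"))
}

#' Write / read a per-cohort EWAS result TSV
#'
#' Dataset-level parameters (prior df, prior variance, consensus correlation,
#' bias, inflation) travel as `#key=value` header comment lines.
#'
#' @param ewas An `EwasResult` from [run_ewas()].
#' @param path Output TSV path.
#' @return `path` (write) or the `EwasResult` (read).
#' @export
write_ewas_result <- function(ewas, path) {
  con <- file(path, "w")
  for (key in c("dataset_id", "d0", "s02", "rho", "mu0", "sigma0")) {
    cat(sprintf("#%s=%s\n", key, format(attr(ewas, key), digits = 15)),
        file = con)
  }
  close(con)
  cols <- c("probe_id", "b", "se", "t", "df_total", "p_raw",
            "z_corr", "p_corr", "se_corr")
  data.table::fwrite(ewas[, cols], path, sep = "\t", na = "NA",
                     quote = FALSE, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_ewas_result
#' @export
read_ewas_result <- function(path) {
  hdr <- readLines(path, n = 20)
  hdr <- hdr[startsWith(hdr, "#")]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  df <- data.table::fread(path, sep = "\t", skip = length(hdr),
                          header = TRUE, data.table = FALSE)
  for (p in kv) {
    val <- if (p[[1]] == "dataset_id") p[[2]] else as.numeric(p[[2]])
    attr(df, p[[1]]) <- val
  }
  df
}
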
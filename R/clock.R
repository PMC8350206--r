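#' Shared probes across datasets
#'
#' @param datasets List of `MethylationDataset`s (>= 2).
#' @return Sorted character vector of probes present in every dataset;
#'   an empty intersection is an error.
#' @export
intersect_probes <- function(datasets) {
  stopifnot(length(datasets) >= 2)
  shared <- Reduce(intersect, lapply(datasets, function(d) rownames(d$beta)))
  if (length(shared) == 0) stopf("no probe is shared by all datasets")
  sort(shared)
}

#' Fit a 3-component beta mixture to methylation values
#'
#' Models the classic trimodal beta-value distribution (unmethylated /
#' hemimethylated / methylated states) with a mixture of beta densities,
#' fitted by EM with a moment-matching M-step. The deterministic
#' quantile-tercile initialization is tried first, followed by jittered
#' restarts; the best-likelihood converged solution is kept and components are
#' returned ordered by mean (so label switching cannot occur). If no restart
#' converges, the quantile-tercile moment fit itself is returned, flagged.
#'
#' @param values Numeric vector in (0, 1); at least 100 finite values.
#' @param k Number of components (3).
#' @param restarts EM restarts (first one deterministic).
#' @param max_fit Subsample cap for the EM (parameters estimated on at most
#'   this many values; classification downstream always uses all values).
#' @param seed Seed for the restart jitter and subsample.
#' @return A `BetaMixture` list: `a`, `b`, `w` (length-k, ordered by mean),
#'   `means`, `loglik`, `method`.
#' @export
fit_beta_mixture <- function(values, k = 3L, restarts = 5L,
                             max_fit = 1000L, seed = 1L) {
  x <- values[is.finite(values)]
  x <- sort(pmin(pmax(x, 1e-6), 1 - 1e-6))
  if (length(x) < 100) stopf("need >= 100 finite values in (0,1)")
  with_seed(substream_seed(seed, "beta-mixture"), {
    # evenly spaced order statistics: deterministic given the value multiset
    # (so identical distributions yield identical fits) and representative
    if (length(x) > max_fit) {
      x <- x[unique(round(seq(1, length(x), length.out = max_fit)))]
    }
    qs <- quantile(x, probs = seq(0, 1, length.out = k + 1))
    moment_ab <- function(v) {
      m <- mean(v); s2 <- max(var(v), 1e-6)
      s2 <- min(s2, 0.99 * m * (1 - m))
      common <- m * (1 - m) / s2 - 1
      c(a = max(m * common, 0.01), b = max((1 - m) * common, 0.01))
    }
    tercile_init <- t(vapply(seq_len(k), function(j) {
      v <- x[x >= qs[j] & x <= qs[j + 1]]
      if (length(v) < 3) v <- x
      moment_ab(v)
    }, c(a = 0, b = 0)))
    fallback <- list(a = tercile_init[, "a"], b = tercile_init[, "b"],
                     w = rep(1 / k, k))
    best <- NULL
    for (r in seq_len(restarts)) {
      jit <- if (r == 1) 1 else exp(rnorm(2 * k, 0, 0.3))
      a0 <- tercile_init[, "a"] * (if (r == 1) 1 else jit[1:k])
      b0 <- tercile_init[, "b"] * (if (r == 1) 1 else jit[(k + 1):(2 * k)])
      em <- .em_beta3(x, a0, b0, rep(1 / k, k), max_iter = 150L)
      if (is.finite(em$loglik) && (is.null(best) || em$loglik > best$loglik)) {
        best <- em
      }
    }
    if (is.null(best)) {
      warnf("beta-mixture EM did not converge; using quantile-tercile fit")
      best <- c(fallback, list(loglik = NA_real_))
      method <- "tercile"
    } else {
      method <- "em"
    }
    ord <- order(best$a / (best$a + best$b))
    structure(list(a = best$a[ord], b = best$b[ord], w = best$w[ord],
                   means = (best$a / (best$a + best$b))[ord],
                   loglik = best$loglik, method = method),
              class = "BetaMixture")
  })
}

#' Classify values to their most likely mixture component
#' @param values Numeric vector in (0,1).
#' @param fit A `BetaMixture`.
#' @return Integer vector of component indices (1 = least methylated).
#' @export
beta_mixture_classify <- function(values, fit) {
  x <- pmin(pmax(values, 1e-6), 1 - 1e-6)
  ll <- vapply(seq_along(fit$a), function(j) {
    log(fit$w[j]) + dbeta(x, fit$a[j], fit$b[j], log = TRUE)
  }, numeric(length(x)))
  if (length(x) == 1) ll <- matrix(ll, nrow = 1)
  max.col(ll, ties.method = "first")
}

#' Build the calibration reference from a gold-standard dataset
#'
#' Fits the 3-component beta mixture to the pooled beta values of the
#' reference dataset and records per-probe mean betas (used to impute probes
#' missing at prediction time) and a quantile summary.
#'
#' @param dataset The gold-standard `MethylationDataset` (by design the
#'   cohort with the widest age range).
#' @param max_fit,seed Passed to [fit_beta_mixture()].
#' @return A `CalibrationReference` list: `dataset_id`, `mixture`,
#'   `probe_means`, `quantiles`.
#' @export
make_calibration_reference <- function(dataset, max_fit = 5000L, seed = 1L) {
  vals <- as.numeric(dataset$beta)
  mix <- fit_beta_mixture(vals, max_fit = max_fit, seed = seed)
  structure(list(
    dataset_id = dataset$dataset_id,
    mixture = mix,
    probe_means = rowMeans(dataset$beta, na.rm = TRUE),
    quantiles = quantile(vals, c(0.01, 0.25, 0.5, 0.75, 0.99), na.rm = TRUE)),
    class = "CalibrationReference")
}

#' Calibrate a dataset to a reference by per-state beta-mixture quantile matching
#'
#' For each sample, fits its own 3-component beta mixture, assigns every probe
#' to its most likely methylation state, and maps each value through its
#' state's fitted CDF into the reference state's inverse CDF. The map is
#' monotone within each state and leaves a sample already distributed like
#' the reference (approximately) unchanged.
#'
#' @param dataset A `MethylationDataset` (probes already reduced to the shared
#'   set).
#' @param reference A `CalibrationReference`.
#' @param seed Seed (per-sample mixture fits are seeded by sample id).
#' @return The dataset with calibrated betas.
#' @export
calibrate_to_reference <- function(dataset, reference, seed = 1L) {
  mix_ref <- reference$mixture
  if (is.null(mix_ref) || length(mix_ref$a) < 3) {
    stopf("calibration reference is missing mixture components")
  }
  beta <- dataset$beta
  for (s in seq_len(ncol(beta))) {
    v <- beta[, s]
    fin <- is.finite(v)
    x <- pmin(pmax(v[fin], 1e-6), 1 - 1e-6)
    fit <- fit_beta_mixture(x, seed = substream_seed(seed, colnames(beta)[s]))
    comp <- beta_mixture_classify(x, fit)
    out <- x
    for (j in seq_along(fit$a)) {
      sel <- comp == j
      if (!any(sel)) next
      u <- pbeta(x[sel], fit$a[j], fit$b[j])
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      out[sel] <- qbeta(u, mix_ref$a[j], mix_ref$b[j])
    }
    v[fin] <- pmin(pmax(out, 1e-6), 1 - 1e-6)
    beta[, s] <- v
  }
  dataset$beta <- beta
  dataset
}

#' Age transform used by the clock (log-linear with an adult knot)
#'
#' `F(age) = log(age + 1) - log(adult_age + 1)` for `age <= adult_age`, and
#' `(age - adult_age)/(adult_age + 1)` above — logarithmic in development,
#' linear in adulthood, continuous and exactly invertible at the knot.
#'
#' @param age Age in years (> -1).
#' @param adult_age Transform knot in years (default 20).
#' @return Transformed age.
#' @export
transform_age <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname transform_age
#' @param t Transformed age.
#' @export
inverse_transform_age <- function(t, adult_age = 20) {
  ifelse(t <= 0,
         exp(t + log(adult_age + 1)) - 1,
         t * (adult_age + 1) + adult_age)
}

#' Train the epigenetic clock by transformed-age elastic net
#'
#' Pools the (calibrated) datasets over their shared probes and fits a
#' penalized linear regression of transformed age on betas with mixing
#' parameter `alpha` (0.5 = elastic net); the penalty strength is chosen by
#' internal k-fold cross-validation minimizing squared error, with fold
#' assignment derived from `seed`. Only nonzero-coefficient probes are
#' retained in the model.
#'
#' @param datasets List of calibrated `MethylationDataset`s.
#' @param reference The `CalibrationReference` the datasets were calibrated
#'   to (stored in the model; its probe means drive imputation at prediction
#'   time).
#' @param alpha Elastic-net mixing parameter.
#' @param nfolds Internal CV folds.
#' @param adult_age Age-transform knot.
#' @param seed Integer seed.
#' @return A `ClockModel` list: `probe_ids`, `coefficients`, `intercept`,
#'   `adult_age`, `alpha`, `lambda`, `reference`, `probe_means`,
#'   `n_training_samples`.
#' @export
train_clock <- function(datasets, reference, alpha = 0.5, nfolds = 10L,
                        adult_age = 20, seed = 1L) {
  shared <- if (length(datasets) == 1) {
    sort(rownames(datasets[[1]]$beta))
  } else {
    intersect_probes(datasets)
  }
  X <- do.call(rbind, lapply(datasets, function(d) {
    t(d$beta[shared, , drop = FALSE])
  }))
  ages <- unlist(lapply(datasets, function(d) d$samples$age))
  if (nrow(X) < 50) stopf("need >= 50 pooled samples to train the clock")
  if (any(!is.finite(ages))) stopf("training ages must be known")
  if (ncol(X) < 2 || all(apply(X[, 1:min(50, ncol(X)), drop = FALSE], 2, sd) == 0)) {
    stopf("degenerate feature matrix")
  }
  y <- transform_age(ages, adult_age)
  foldid <- with_seed(substream_seed(seed, "clock-folds"),
                      sample(rep(seq_len(nfolds), length.out = nrow(X))))
  cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                          standardize = TRUE)
  co <- as.matrix(coef(cv, s = "lambda.min"))
  nz <- which(co[-1, 1] != 0)
  structure(list(
    probe_ids = shared[nz],
    coefficients = unname(co[-1, 1][nz]),
    intercept = unname(co[1, 1]),
    adult_age = adult_age, alpha = alpha,
    lambda = cv$lambda.min,
    reference = reference,
    probe_means = unname(reference$probe_means[shared[nz]]),
    n_training_samples = nrow(X)), class = "ClockModel")
}

#' @exportS3Method base::print
print.ClockModel <- function(x, ...) {
  cat(sprintf(
    "ClockModel: %d CpGs, intercept %.4f, adult_age %g, trained on %d samples (reference '%s')\n",
    length(x$probe_ids), x$intercept, x$adult_age, x$n_training_samples,
    x$reference$dataset_id))
  invisible(x)
}

#' Predict age from methylation with a trained clock
#'
#' `age_hat = Finv(intercept + sum coef * beta)`. The dataset must be
#' calibrated to the model's reference; model probes missing from the dataset
#' are imputed with the reference probe means (an error above 20% missing).
#'
#' @param model A `ClockModel`.
#' @param dataset A calibrated `MethylationDataset`.
#' @return Numeric vector of predicted ages (years), named by sample.
#' @export
predict_age <- function(model, dataset) {
  if (length(model$probe_ids) == 0) {
    # intercept-only model (penalty removed every probe)
    return(setNames(rep(inverse_transform_age(model$intercept,
                                              model$adult_age),
                        ncol(dataset$beta)),
                    colnames(dataset$beta)))
  }
  idx <- match(model$probe_ids, rownames(dataset$beta))
  n_missing <- sum(is.na(idx))
  if (n_missing > 0.2 * length(idx)) {
    stopf("%d of %d clock probes missing from dataset", n_missing,
          length(idx))
  }
  B <- matrix(rep(model$probe_means, ncol(dataset$beta)),
              nrow = length(idx))
  B[!is.na(idx), ] <- dataset$beta[idx[!is.na(idx)], , drop = FALSE]
  B[is.na(B)] <- model$probe_means[which(is.na(B), arr.ind = TRUE)[, 1]]
  t_hat <- model$intercept + as.numeric(crossprod(B, model$coefficients))
  setNames(inverse_transform_age(t_hat, model$adult_age),
           colnames(dataset$beta))
}

#' Leave-one-dataset-out evaluation of the clock
#'
#' For each dataset in turn: pick the widest-age-range training dataset as
#' the calibration gold standard, calibrate all training datasets (the
#' reference itself is left untouched), train the clock, calibrate the
#' held-out dataset to the same reference, and predict its ages. The held-out
#' dataset influences neither the reference choice nor the penalty selection.
#' Per-dataset accuracy is the Pearson correlation and median absolute error;
#' the aggregate is the mean correlation (datasets with undefined r excluded)
#' and the median of the per-dataset median errors.
#'
#' @param datasets List of >= 3 `MethylationDataset`s (uncalibrated; probes
#'   reduced internally to the shared set).
#' @param alpha,nfolds,adult_age Passed to [train_clock()].
#' @param seed Integer seed.
#' @return A `ClockEvaluation` list: `per_dataset` data frame (`dataset_id`,
#'   `n`, `r`, `median_abs_error`, `mean_error`), `mean_r`,
#'   `median_abs_error`.
#' @export
lodo_evaluate <- function(datasets, alpha = 0.5, nfolds = 10L,
                          adult_age = 20, seed = 1L) {
  if (length(datasets) < 3) stopf("need >= 3 datasets for leave-one-dataset-out")
  shared <- intersect_probes(datasets)
  datasets <- lapply(datasets, function(d) {
    d$beta <- d$beta[shared, , drop = FALSE]
    d
  })
  rows <- vector("list", length(datasets))
  # calibration of a dataset depends only on (dataset, reference, seed), so
  # memoize across LODO rounds — most rounds share the same gold standard
  ref_cache <- new.env(parent = emptyenv())
  cal_cache <- new.env(parent = emptyenv())
  get_reference <- function(ref_dataset) {
    key <- ref_dataset$dataset_id
    if (is.null(ref_cache[[key]])) {
      ref_cache[[key]] <- make_calibration_reference(ref_dataset, seed = seed)
    }
    ref_cache[[key]]
  }
  get_calibrated <- function(d, reference) {
    key <- paste(d$dataset_id, reference$dataset_id, sep = "\r")
    if (is.null(cal_cache[[key]])) {
      cal_cache[[key]] <- calibrate_to_reference(d, reference, seed = seed)
    }
    cal_cache[[key]]
  }
  for (i in seq_along(datasets)) {
    held <- datasets[[i]]
    train <- datasets[-i]
    ranges <- vapply(train, function(d) diff(range(d$samples$age)), 0)
    ref_dataset <- train[[which.max(ranges)]]
    reference <- get_reference(ref_dataset)
    train_cal <- lapply(train, function(d) {
      if (identical(d$dataset_id, ref_dataset$dataset_id)) d
      else get_calibrated(d, reference)
    })
    model <- train_clock(train_cal, reference, alpha = alpha,
                         nfolds = nfolds, adult_age = adult_age, seed = seed)
    held_cal <- get_calibrated(held, reference)
    pred <- predict_age(model, held_cal)
    actual <- held$samples$age
    r <- if (sd(actual) == 0 || sd(pred) == 0) NA_real_ else cor(pred, actual)
    if (is.na(r)) warnf("correlation undefined for dataset '%s'", held$dataset_id)
    rows[[i]] <- data.frame(
      dataset_id = held$dataset_id, n = length(pred), r = r,
      median_abs_error = median(abs(pred - actual)),
      mean_error = mean(pred - actual), stringsAsFactors = FALSE)
  }
  per_dataset <- do.call(rbind, rows)
  structure(list(
    per_dataset = per_dataset,
    mean_r = mean(per_dataset$r, na.rm = TRUE),
    median_abs_error = median(per_dataset$median_abs_error)),
    class = "ClockEvaluation")
}

#' Serialize / restore a clock model as a single JSON document
#'
#' The document carries the probe list, coefficients, intercept, transform
#' knot, penalty metadata, the calibration-reference mixture parameters and
#' quantile summary, and the per-probe reference means; a round-trip restores
#' identical predictions.
#'
#' @param model A `ClockModel`.
#' @param path JSON file path.
#' @return `path` (write) or the `ClockModel` (read).
#' @export
write_clock_model <- function(model, path) {
  doc <- list(
    probe_ids = model$probe_ids,
    coefficients = model$coefficients,
    intercept = model$intercept,
    adult_age = model$adult_age,
    alpha = model$alpha,
    lambda = model$lambda,
    probe_means = model$probe_means,
    n_training_samples = model$n_training_samples,
    reference = list(
      dataset_id = model$reference$dataset_id,
      mixture = model$reference$mixture[c("a", "b", "w", "means")],
      quantiles = as.list(model$reference$quantiles)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- structure(list(
    dataset_id = doc$reference$dataset_id,
    mixture = structure(doc$reference$mixture, class = "BetaMixture"),
    probe_means = setNames(doc$probe_means, doc$probe_ids),
    quantiles = unlist(doc$reference$quantiles)),
    class = "CalibrationReference")
  structure(list(
    probe_ids = doc$probe_ids,
    coefficients = doc$coefficients,
    intercept = doc$intercept,
    adult_age = doc$adult_age,
    alpha = doc$alpha,
    lambda = doc$lambda,
    reference = ref,
    probe_means = doc$probe_means,
    n_training_samples = doc$n_training_samples), class = "ClockModel")
}
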
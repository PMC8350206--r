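#' Estimate the empirical null of a vector of z-scores
#'
#' Unmeasured technical and biological confounding (batch effects, cellular
#' heterogeneity, population substructure) biases and inflates EWAS test
#' statistics. This models the observed signed z-scores as a three-component
#' Gaussian mixture: a central null component with mean `mu0` (bias) and sd
#' `sigma0` (inflation), plus a negative-mean and a positive-mean alternative
#' component whose sds are constrained to be at least `sigma0`. The mixture is
#' fitted by EM from several random restarts (weight of the null initialized
#' at 0.9) and the best log-likelihood solution is kept. If no restart
#' converges, a robust null (`median`, `MAD`) is used and flagged.
#'
#' @param z Numeric vector of z-scores (non-finite values dropped). Fewer
#'   than 1000 finite values triggers the robust fallback directly.
#' @param restarts Number of EM restarts.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param seed Seed for the restart jitter.
#' @return A list: `mu0`, `sigma0`, `pi0`, `loglik`, `method`
#'   (`"em"` or `"robust"`).
#' @export
estimate_empirical_null <- function(z, restarts = 10L, max_iter = 400L,
                                    tol = 1e-7, seed = 1L) {
  z <- z[is.finite(z)]
  robust <- list(mu0 = median(z), sigma0 = mad(z), pi0 = 1,
                 loglik = NA_real_, method = "robust")
  if (length(z) < 1000) {
    warnf("only %d finite z-scores; using robust empirical null", length(z))
    return(robust)
  }
  m <- median(z)
  s <- mad(z)
  best <- NULL
  with_seed(substream_seed(seed, "empirical-null"), {
    for (r in seq_len(restarts)) {
      jit <- if (r == 1) c(0, 0) else c(rnorm(1, 0, 0.1 * s), runif(1, 0.8, 1.2))
      mu_init <- c(m + jit[1], m - (3 + runif(1)) * s, m + (3 + runif(1)) * s)
      sd_init <- c(s * (if (r == 1) 1 else jit[2]), 2 * s, 2 * s)
      w_init <- c(0.9, 0.05, 0.05)
      em <- .em_gaussian3(z, mu_init, sd_init, w_init,
                          max_iter = max_iter, tol = tol)
      if (em$converged &&
          (is.null(best) || em$loglik > best$loglik)) {
        best <- em
      }
    }
  })
  if (is.null(best)) {
    warnf("empirical-null EM did not converge in any restart; robust fallback")
    return(robust)
  }
  list(mu0 = best$mu[1], sigma0 = best$sd[1], pi0 = best$w[1],
       loglik = best$loglik, method = "em")
}

#' Correct z-scores for estimated bias and inflation
#'
#' `z' = (z - mu0) / sigma0` with two-sided normal p-values
#' `p' = 2 * pnorm(-|z'|)`.
#'
#' @param z Vector of z-scores.
#' @param mu0 Estimated bias.
#' @param sigma0 Estimated inflation (> 0).
#' @return List with corrected `z` and `p`.
#' @export
apply_empirical_null <- function(z, mu0, sigma0) {
  stopifnot(sigma0 > 0)
  zc <- (z - mu0) / sigma0
  list(z = zc, p = 2 * pnorm(-abs(zc)))
}
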
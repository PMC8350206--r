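test_that("the age coefficient matches ordinary least squares exactly", {
  # perfect line: 0.002 beta per year
  beta <- rbind(cg1 = 0.50 + 0.002 * c(0, 10, 20, 30),
                cg2 = rep(0.5, 4))
  ds <- make_dataset(beta, ages = c(20, 30, 40, 50))
  fit <- fit_age_models(ds, covariates = character(0))
  expect_equal(fit$b[1], 0.002, tolerance = 1e-12)
  expect_equal(fit$s2[1], 0, tolerance = 1e-20)
  expect_true(fit$degenerate[1])  # zero residual variance
  expect_equal(fit$b[2], 0, tolerance = 1e-12)
  expect_true(fit$degenerate[2])
})

test_that("covariate-adjusted fits equal the normal-equations solution", {
  ages <- c(23, 34, 45, 56, 67, 78)
  sex <- c("F", "M", "F", "M", "F", "M")
  y <- c(0.31, 0.42, 0.36, 0.50, 0.44, 0.58)
  ds <- make_dataset(rbind(cg1 = y, cg2 = rev(y)), ages = ages, sex = sex)
  fit <- fit_age_models(ds, covariates = "sex")
  X <- cbind(1, ages, as.numeric(sex == "M"))
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$b[1], oracle[2], tolerance = 1e-10)
  res <- y - X %*% oracle
  expect_equal(fit$s2[1], sum(res^2) / (6 - 3), tolerance = 1e-10)
  expect_equal(fit$df[1], 3)
})

test_that("design building drops unusable covariates and guards age", {
  ds <- make_dataset(matrix(runif(8), 2, 4), ages = c(20, 30, 40, 50),
                     sex = rep("M", 4), bmi = c(22, 25, 27, 24))
  w <- capture_warnings(d <- build_design(ds$samples, c("sex", "bmi", "t2d")))
  expect_true(any(grepl("constant", w)))
  expect_true(any(grepl("absent", w)))
  expect_identical(d$used, "bmi")
  ds2 <- make_dataset(matrix(runif(8), 2, 4), ages = rep(44, 4))
  expect_error(build_design(ds2$samples, character(0)), "age is constant")
  # a covariate aliased with age triggers the rank-deficiency guard: either
  # the aliased column is dropped with a warning or, if age itself would be
  # lost, a hard error
  ds3 <- make_dataset(matrix(runif(8), 2, 4), ages = c(20, 30, 40, 50),
                      bmi = c(20, 30, 40, 50))
  expect_condition(build_design(ds3$samples, "bmi"),
                   regexp = "rank-deficient|confounded")
})

test_that("variance moderation shrinks between s2 and the prior", {
  set.seed(1)
  n <- 200
  fit <- data.frame(probe_id = paste0("cg", 1:n),
                    b = rnorm(n, 0, 0.001),
                    stdev_unscaled = rep(0.05, n),
                    s2 = rchisq(n, df = 8) / 8 * 0.01,
                    df = rep(8, n), se_raw = NA, degenerate = FALSE)
  mod <- moderate_statistics(fit)
  d0 <- attr(mod, "d0")
  s02 <- attr(mod, "s02")
  lo <- pmin(mod$s2, s02)
  hi <- pmax(mod$s2, s02)
  expect_true(all(mod$s2_post >= lo - 1e-12 & mod$s2_post <= hi + 1e-12))
  if (is.finite(d0)) {
    expect_equal(mod$s2_post, (d0 * s02 + mod$df * mod$s2) / (d0 + mod$df),
                 tolerance = 1e-9)
  }
  expect_equal(mod$t, mod$b / (mod$stdev_unscaled * sqrt(mod$s2_post)),
               tolerance = 1e-12)
  expect_equal(mod$p_raw, 2 * pt(-abs(mod$t), mod$df_total),
               tolerance = 1e-12)
})

test_that("cohorts without repeated measures reduce to ordinary least squares", {
  ds <- make_dataset(matrix(runif(40, 0.3, 0.7), 4, 10),
                     ages = seq(21, 66, 5))
  expect_identical(estimate_consensus_correlation(ds), 0)
  f0 <- fit_age_models(ds, covariates = character(0))
  f1 <- fit_age_models(ds, covariates = character(0), rho = 1e-9)
  expect_equal(f0$b, f1$b, tolerance = 1e-10)
  expect_equal(f0$s2, f1$s2, tolerance = 1e-8)
})

test_that("the consensus correlation tracks the subject random effect", {
  d <- scaled_design()[2, ]  # repeated-measures cohort
  d$n_subjects <- 40L
  strong <- sim_config(cohorts = d, n_probes = 300, slope_scale = 0,
                       subject_sd = 0.5, noise_sd = 0.1, batch_sd = 0)
  toy <- build_toy_annotation(strong, seed = 9)
  sim <- simulate_multicohort(toy, strong, seed = 9)
  rho_hi <- suppressWarnings(estimate_consensus_correlation(sim$datasets[[1]]))
  expect_gt(rho_hi, 0.8)

  none <- sim_config(cohorts = d, n_probes = 200, slope_scale = 0,
                     subject_sd = 0, noise_sd = 0.1, batch_sd = 0)
  toy0 <- build_toy_annotation(none, seed = 9)
  sim0 <- simulate_multicohort(toy0, none, seed = 9)
  rho_0 <- suppressWarnings(estimate_consensus_correlation(sim0$datasets[[1]]))
  expect_lt(abs(rho_0), 0.05)
})

test_that("the empirical null recovers bias and inflation", {
  # identity null on exact standard-normal quantiles
  z <- qnorm(seq_len(10001) / 10002)
  en <- estimate_empirical_null(z, seed = 1)
  expect_lt(abs(en$mu0), 0.01)
  expect_lt(abs(en$sigma0 - 1), 0.02)

  # known bias and inflation
  set.seed(77)
  z2 <- 0.15 + 1.4 * rnorm(50000)
  en2 <- estimate_empirical_null(z2, seed = 1)
  expect_lt(abs(en2$mu0 - 0.15), 0.02)
  expect_lt(abs(en2$sigma0 - 1.4), 0.03)

  # contamination: 10% shifted +4 barely moves the null component
  set.seed(78)
  z3 <- c(rnorm(45000), rnorm(5000, 4))
  en3 <- estimate_empirical_null(z3, seed = 1)
  expect_lt(abs(en3$mu0), 0.03)
  expect_lt(abs(en3$sigma0 - 1), 0.05)

  expect_warning(estimate_empirical_null(rnorm(100), seed = 1), "robust")
})

test_that("applying the empirical null rescales z and p consistently", {
  expect_equal(apply_empirical_null(1.7, 0, 1)$z, 1.7)
  out <- apply_empirical_null(2.6, 0.1, 1.25)
  expect_equal(out$z, 2.0, tolerance = 1e-12)
  expect_equal(out$p, 2 * pnorm(-2), tolerance = 1e-12)
  # sign symmetry
  expect_equal(apply_empirical_null(-2.6, -0.1, 1.25)$z, -2.0,
               tolerance = 1e-12)
  expect_error(apply_empirical_null(1, 0, 0))
})

test_that("probit z-scores carry the sign and the two-sided tail", {
  p <- c(0.0455, 0.5, 1e-10)
  t <- c(2.1, -0.5, -9)
  z <- probit_z(p, t)
  expect_equal(z, sign(t) * qnorm(p / 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(all(is.finite(probit_z(1e-320, 5))))
})

test_that("a cohort EWAS result round-trips through its TSV", {
  sim <- small_sim()
  e <- sim$pipe$ewas[[1]]
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_ewas_result(e, tmp)
  back <- read_ewas_result(tmp)
  expect_equal(back$b, e$b, tolerance = 1e-12)
  expect_equal(attr(back, "sigma0"), attr(e, "sigma0"), tolerance = 1e-12)
  expect_identical(attr(back, "dataset_id"), attr(e, "dataset_id"))
})
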
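# EM machinery: likelihood oracle, conditional posterior limits, marginal
# likelihood vs quadrature, LRT arithmetic, residual calibration, and
# seeded determinism.

test_that("individual log-likelihood matches a direct density computation", {
  s <- make_subject("L1", sigma = 0.07, seed = 3)
  lt <- log(unclass(ref_params())) + c(0.1, -0.2, 0.05, -0.04)
  sig <- 0.08
  ll <- individual_loglik(s, lt, sig)
  f <- simulate_glucose(exp(lt), s$dose, s$Gbasal, s$Ibasal, s$forcing,
                        s$obs_times)
  ll_direct <- sum(dnorm(s$obs_glucose, mean = f, sd = sig * f, log = TRUE))
  expect_equal(ll, ll_direct, tolerance = 1e-8)

  # zero residuals: only the normalization terms remain
  s0 <- make_subject("L2", sigma = 0)
  lt0 <- log(unclass(ref_params()))
  f0 <- simulate_glucose(ref_params(), s0$dose, s0$Gbasal, s0$Ibasal,
                         s0$forcing, s0$obs_times)
  expect_equal(individual_loglik(s0, lt0, sig),
               sum(-log(sig * f0 * sqrt(2 * pi))), tolerance = 1e-7)
  # doubling sigma with zero residuals costs n*log(2)
  expect_equal(individual_loglik(s0, lt0, sig) -
                 individual_loglik(s0, lt0, 2 * sig),
               length(s0$obs_times) * log(2), tolerance = 1e-7)
})

test_that("conditional posterior collapses to the prior or the data as expected", {
  s <- make_subject("C1", sigma = 0.07, seed = 9)
  mu <- log(unclass(ref_params()))
  st <- quick_settings(seed = 2)

  # near-degenerate prior: conditional mean pinned at the population mean
  tiny <- population_params(mu, diag(4) * 1e-8, list(), 0.07)
  r1 <- conditional_posterior(s, tiny, st)
  expect_equal(r1$mean, mu, tolerance = 1e-3)

  # huge residual error: data uninformative, conditional mean near prior mean
  wide <- population_params(mu, diag(4) * 0.04, list(), 50)
  r2 <- conditional_posterior(s, wide, st)
  expect_equal(r2$mean, mu, tolerance = 0.05)
  expect_gt(r2$ess, 10)

  # rich noiseless data at known parameters: conditional mean within 1%
  truth <- mm_params(0.016, 6e-5, 0.05, 11)
  s3 <- make_subject("C2", params = truth, sigma = 0,
                     times = c(5, 6, 8, 10, 13, 16, 20, 25, 30, 40, 50, 65,
                               80, 100, 120, 150, 180))
  pop3 <- population_params(mu, diag(4) * 0.3, list(),
                            sigma_prop = 1e-4)
  r3 <- conditional_posterior(s3, pop3, fit_settings(seed = 4))
  expect_equal(unname(r3$mean), unname(log(unclass(truth))), tolerance = 0.01)
  expect_true(all(eigen(r3$cov, symmetric = TRUE)$values >= 0))
  expect_equal(sum(r3$weights), 1, tolerance = 1e-12)
})

test_that("importance-sampled -2LL matches Gauss-Hermite quadrature on a toy set", {
  # small IIV so a prior-centered tensor quadrature is itself accurate
  mu <- log(unclass(ref_params()))
  pop <- population_params(mu, diag(4) * 0.05^2, list(), 0.05)
  ds <- lapply(1:3, function(i) {
    set.seed(300 + i)
    th <- exp(mu + 0.05 * rnorm(4))
    make_subject(paste0("Q", i), params = mm_params(th[1], th[2], th[3], th[4]),
                 sigma = 0.05, seed = 400 + i)
  })
  m2_is <- total_minus2LL(ds, pop, fit_settings(seed = 8), n_samples = 2000)

  gh <- pracma::gaussHermite(10)
  idx <- expand.grid(1:10, 1:10, 1:10, 1:10)
  Wt <- gh$w[idx[, 1]] * gh$w[idx[, 2]] * gh$w[idx[, 3]] * gh$w[idx[, 4]]
  Xn <- cbind(gh$x[idx[, 1]], gh$x[idx[, 2]], gh$x[idx[, 3]], gh$x[idx[, 4]])
  tot <- 0
  U <- sweep(sqrt(2) * 0.05 * Xn, 2, mu, "+")
  for (s in ds) {
    ll <- mmpop:::mm_loglik_cpp(U, s$dose, s$Gbasal, s$Ibasal,
                                s$forcing$times, s$forcing$concentrations,
                                s$obs_times, s$obs_glucose,
                                pop$sigma_prop, 1e-8, 1e-10)[, 1]
    a <- max(ll)
    tot <- tot + (a + log(sum(Wt * exp(ll - a))) - log(pi^2))
  }
  expect_equal(as.numeric(m2_is), -2 * tot, tolerance = 0.5)
})

test_that("repeated marginal-likelihood evaluation concentrates with sample size", {
  s <- make_subject("V1", sigma = 0.07, seed = 13)
  pop <- population_params(log(unclass(ref_params())), diag(4) * 0.09,
                           list(), 0.07)
  vals_small <- vapply(1:6, function(k)
    as.numeric(total_minus2LL(list(s), pop, fit_settings(seed = k), n_samples = 50)), 0)
  vals_big <- vapply(1:6, function(k)
    as.numeric(total_minus2LL(list(s), pop, fit_settings(seed = k), n_samples = 1000)), 0)
  expect_lt(var(vals_big), var(vals_small))
})

test_that("the likelihood-ratio test reproduces chi-square arithmetic", {
  # published base-vs-final objective functions
  out <- lrt(18674, 18115, df = 5)
  expect_lt(out$p_value, 1e-6)
  expect_equal(out$statistic, 559)
  expect_equal(lrt(1234.5, 1234.5, df = 1)$p_value, 1)
  expect_equal(lrt(103.841, 100, df = 1)$p_value, 0.05, tolerance = 1e-3)
  expect_error(lrt(100, 105, df = 1), class = "mmpop_invalid_argument")
  expect_error(lrt(100, 99, df = 0), class = "mmpop_invalid_argument")
})

test_that("conditional standardized residuals are calibrated", {
  set.seed(77)
  pop <- population_params(log(unclass(ref_params())),
                           diag(c(0.15, 0.3, 0.15, 0.08)^2), list(), 0.07)
  ds <- lapply(1:25, function(i) {
    th <- sample_individual(pop, list())
    make_subject(sprintf("R%02d", i), params = th, sigma = 0.07,
                 seed = 500 + i)
  })
  fit <- suppressWarnings(em_fit(ds, settings = fit_settings(
    n_importance_samples = 80, max_iterations = 12, seed = 6)))
  rs <- conditional_std_residuals(fit, ds)
  expect_equal(nrow(rs), sum(vapply(ds, function(s) length(s$obs_times), 0L)))
  expect_lt(abs(mean(rs$residual)), 3 / sqrt(nrow(rs)) * 1.5 + 0.05)
  expect_gt(var(rs$residual), 0.6)
  expect_lt(var(rs$residual), 1.4)

  # noiseless self-simulated data: residuals collapse
  ds0 <- make_dataset(n = 10, sigma = 1e-6)
  fit0 <- suppressWarnings(em_fit(ds0, settings = quick_settings(seed = 7)))
  rs0 <- conditional_std_residuals(fit0, ds0)
  expect_lt(max(abs(rs0$residual)) * fit0$pop$sigma_prop, 0.02)
})

test_that("fits are bit-reproducible and subject-order invariant", {
  ds <- make_dataset(n = 10, sigma = 0.05)
  st <- quick_settings(seed = 11)
  f1 <- suppressWarnings(em_fit(ds, settings = st))
  f2 <- suppressWarnings(em_fit(ds, settings = st))
  expect_identical(f1$pop, f2$pop)
  expect_identical(f1$conditional_mean_log, f2$conditional_mean_log)

  # permutation changes only summation order; chaotic amplification through
  # the optimizer keeps agreement at Monte-Carlo precision, not bit level
  perm <- c(4, 1, 10, 3, 7, 2, 9, 5, 8, 6)
  f3 <- suppressWarnings(em_fit(ds[perm], settings = st))
  expect_equal(typical_values(f3$pop), typical_values(f1$pop), tolerance = 1e-2)
  expect_equal(f3$pop$sigma_prop, f1$pop$sigma_prop, tolerance = 1e-2)
})

test_that("EM recovers the truth under degenerate noise", {
  truth <- ref_params()
  ds <- make_dataset(n = 12, params = truth, sigma = 1e-4)
  fit <- suppressWarnings(em_fit(ds, settings = fit_settings(
    n_importance_samples = 60, max_iterations = 20, seed = 21)))
  expect_equal(unname(typical_values(fit$pop)), unname(unclass(truth)),
               tolerance = 0.01)
  expect_lt(fit$pop$sigma_prop, 0.01)
})

test_that("Sigma stays SPD and the smoothed -2LL trace does not increase", {
  set.seed(31)
  pop <- population_params(log(unclass(ref_params())),
                           diag(c(0.2, 0.4, 0.2, 0.1)^2), list(), 0.07)
  ds <- lapply(1:15, function(i) {
    th <- sample_individual(pop, list())
    make_subject(sprintf("T%02d", i), params = th, sigma = 0.07, seed = 600 + i)
  })
  fit <- suppressWarnings(em_fit(ds, settings = fit_settings(
    n_importance_samples = 80, max_iterations = 15, seed = 9)))
  expect_true(is_spd_fit <- all(eigen(fit$pop$Sigma_log)$values > 0))
  m2 <- fit$trace$minus2LL
  sm <- stats::filter(m2, rep(1 / 3, 3), sides = 1)
  sm <- sm[!is.na(sm)]
  mc_band <- 6 * attr(fit$minus2LL, "mc_se") + 3
  expect_true(all(diff(sm) < mc_band))
})

test_that("standard errors scale like 1/sqrt(n) and flag degenerate fits", {
  ds <- make_dataset(n = 12, sigma = 0.05)
  st <- quick_settings(seed = 15)
  fit <- suppressWarnings(em_fit(ds, settings = st))
  se <- suppressWarnings(standard_errors(fit, ds, st))
  expect_true(all(is.finite(se$rse[paste0("TV_", mmpop:::MM_PARS)])))
  expect_true(all(se$rse[paste0("TV_", mmpop:::MM_PARS)] > 0))

  ds2 <- make_dataset(n = 24, sigma = 0.05)
  fit2 <- suppressWarnings(em_fit(ds2, settings = st))
  se2 <- suppressWarnings(standard_errors(fit2, ds2, st))
  ratio <- se2$rse["TV_V"] / se$rse["TV_V"]
  expect_lt(ratio, 1.05)

  # a zero-variance fit must travel the singular-information warning path
  fit_deg <- fit
  fit_deg$pop$Sigma_log <- diag(4) * 1e-9
  dimnames(fit_deg$pop$Sigma_log) <- dimnames(fit$pop$Sigma_log)
  expect_warning(standard_errors(fit_deg, ds, st), "singular|pseudo")
})
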
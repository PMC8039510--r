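# Forward model: dose conversion, insulin interpolation, ODE solution
# against analytic and brute-force oracles, and the early-sample filter.

test_that("dose conversion to mmol is correct and proportional", {
  expect_equal(dose_to_mmol(0.3, 75), 0.3 * 75 * 1000 / 180.16)
  expect_equal(dose_to_mmol(0.3, 75), 124.889, tolerance = 1e-4)
  expect_equal(dose_to_mmol(0.3, 100), dose_to_mmol(0.3, 75) * 4 / 3)
  expect_lt(dose_to_mmol(0.3, 1e-9), 1e-6)
  expect_error(dose_to_mmol(0, 75), class = "mmpop_invalid_argument")
  expect_error(dose_to_mmol(0.3, -1), class = "mmpop_invalid_argument")
})

test_that("insulin interpolation is linear with constant extrapolation", {
  f <- insulin_forcing(c(0, 10), c(100, 300), 40)
  expect_equal(interpolate_insulin(f, 10), 300)
  expect_equal(interpolate_insulin(f, 5), 200)
  expect_equal(interpolate_insulin(f, 25), 300)
  expect_equal(interpolate_insulin(f, 0), 100)
  expect_error(insulin_forcing(5, 100, 40), class = "mmpop_invalid_argument")
  expect_error(insulin_forcing(c(0, 0), c(1, 2), 40), class = "mmpop_invalid_argument")
  expect_error(insulin_forcing(c(0, 10), c(-1, 2), 40), class = "mmpop_invalid_argument")
})

test_that("constant-insulin closed form matches its analytic limits", {
  p <- mm_params(0.02, 5e-5, 0.04, 12)
  expect_equal(glucose_closed_form_constant_insulin(p, 120, 5, 40, 0), 5 + 10)
  expect_equal(glucose_closed_form_constant_insulin(p, 120, 5, 40, 1e6), 5)
  # GEZI + SI*Ib = 0.022 -> at t = 50, exponent 1.1
  expect_equal(glucose_closed_form_constant_insulin(p, 120, 5, 40, 50),
               5 + 10 * exp(-1.1), tolerance = 1e-10)
  expect_equal(5 + 10 * exp(-1.1), 8.3287, tolerance = 1e-4)
})

test_that("simulated glucose starts at Gbasal + Dose/V", {
  p <- mm_params(0.015, 4e-5, 0.03, 10)
  g0 <- simulate_glucose(p, 100, 5.5, 60, biphasic_forcing(60), 0)
  expect_equal(g0, 5.5 + 100 / 10)
})

test_that("adaptive solution matches the closed form under constant insulin", {
  p <- mm_params(0.02, 5e-5, 0.04, 12)
  tt <- c(0, 1, 5, 10, 25, 50, 100, 180, 360)
  g_num <- simulate_glucose(p, 124.89, 5, 40, const_forcing(40), tt)
  g_cf <- glucose_closed_form_constant_insulin(p, 124.89, 5, 40, tt)
  expect_equal(g_num, g_cf, tolerance = 1e-6)
})

test_that("steady state is preserved with zero dose and basal insulin", {
  p <- mm_params(0.02, 5e-5, 0.04, 12)
  tt <- seq(0, 360, by = 30)
  st <- simulate_glucose(p, 1e-12, 5, 40, const_forcing(40), tt,
                         return_state = TRUE)
  expect_equal(st$G, rep(5, length(tt)), tolerance = 1e-8)
  expect_equal(st$X, rep(5e-5 * 40, length(tt)), tolerance = 1e-8)
})

test_that("adaptive solver agrees with the fixed-step brute-force oracle", {
  # the documented biphasic reference case
  p <- mm_params(0.02, 5e-5, 0.04, 12)
  fb <- biphasic_forcing(40)
  tt <- c(0, 3, 5, 8, 12, 20, 30, 45, 60, 90, 120, 180)
  g_ad <- simulate_glucose(p, 124.89, 5, 40, fb, tt)
  or <- mmpop:::mm_simulate_fixed_cpp(unclass(p), 124.89, 5, 40,
                                      fb$times, fb$concentrations, tt, 0.001)
  expect_equal(g_ad, or[, 1], tolerance = 1e-4)

  # random parameter/forcing draws
  set.seed(99)
  for (k in 1:10) {
    th <- mm_params(exp(rnorm(1, log(0.018), 0.4)),
                    exp(rnorm(1, log(4e-5), 0.8)),
                    exp(rnorm(1, log(0.04), 0.4)),
                    exp(rnorm(1, log(12), 0.3)))
    Ib <- runif(1, 30, 150)
    f <- biphasic_forcing(Ib)
    dose <- runif(1, 90, 180)
    g1 <- simulate_glucose(th, dose, runif(1, 4, 9), Ib, f, tt)
    g2 <- mmpop:::mm_simulate_fixed_cpp(unclass(th), dose,
                                        g1[1] - dose / unclass(th)[["V"]], Ib,
                                        f$times, f$concentrations, tt, 0.001)[, 1]
    expect_equal(g1, g2, tolerance = 1e-4)
  }
})

test_that("increasing GEZI speeds glucose disappearance above basal", {
  # while G(t) > Gbasal a larger GEZI always lowers G(t); once G undershoots
  # basal the return-to-basal source term reverses the sensitivity, so the
  # comparison is made in the no-undershoot regime (small insulin action)
  tt <- c(5, 15, 30, 60, 120, 180)
  f <- const_forcing(40)  # X stays at basal: G approaches Gb from above
  gz <- seq(0.005, 0.05, length.out = 6)
  G <- sapply(gz, function(g)
    simulate_glucose(mm_params(g, 5e-5, 0.04, 12), 124.89, 5, 40, f, tt))
  expect_true(all(G > 5 - 1e-6))
  expect_true(all(diff(t(G)) <= 1e-8))
})

test_that("simulated glucose stays positive across random draws", {
  set.seed(123)
  tt <- seq(0, 240, by = 5)
  for (k in 1:20) {
    th <- mm_params(exp(rnorm(1, log(0.018), 0.6)),
                    exp(rnorm(1, log(4e-5), 1.1)),
                    exp(rnorm(1, log(0.04), 0.5)),
                    exp(rnorm(1, log(12), 0.35)))
    g <- simulate_glucose(th, runif(1, 80, 200), runif(1, 4, 10),
                          runif(1, 30, 150), biphasic_forcing(60, 240), tt)
    expect_true(all(g > 0))
  }
})

test_that("early-sample filter drops t < 5 and keeps the boundary", {
  f <- biphasic_forcing(40)
  s <- subject_data("A", "IVGTT", 120, c(2, 4, 5, 8, 20, 60),
                    c(15, 14, 13, 12, 9, 6), f, 5, 40)
  s2 <- filter_early_samples(s)
  expect_equal(s2$obs_times, c(5, 8, 20, 60))
  expect_equal(s2$obs_glucose, c(13, 12, 9, 6))
  expect_identical(s2$forcing, s$forcing)

  s3 <- subject_data("B", "IVGTT", 120, c(5, 8, 20, 60), c(13, 12, 9, 6),
                     f, 5, 40)
  expect_identical(filter_early_samples(s3)$obs_times, s3$obs_times)

  s4 <- subject_data("C", "IVGTT", 120, c(0, 1, 2, 8, 20), c(15, 15, 14, 12, 9),
                     f, 5, 40)
  expect_error(filter_early_samples(s4), class = "mmpop_data_insufficiency")
})
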
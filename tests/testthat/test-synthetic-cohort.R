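# Virtual-trial generator: covariate marginals, imputation rules, insulin
# profiles, schedules, noise model and determinism.

test_that("generated covariates match the target marginals", {
  spec <- cohort_spec(n_subjects = 5000, seed = 11)
  tb <- generate_covariates(spec)
  expect_equal(nrow(tb), 5000)
  # pooled targets
  expect_lt(abs(mean(tb$age_yr) - 41.4), 3 * 16.9 / sqrt(5000))
  expect_lt(abs(mean(tb$bmi_kg_m2) - 28.0), 3 * 6.76 / sqrt(5000))
  expect_lt(abs(mean(tb$height_cm) - 169), 3 * 10.1 / sqrt(5000))
  # internal consistency of the anthropometry
  expect_equal(tb$bmi_kg_m2, tb$weight_kg / (tb$height_cm / 100)^2)
  # truncation bounds
  expect_true(all(tb$age_yr >= 9.7 & tb$age_yr <= 86))
  expect_true(all(tb$bmi_kg_m2 >= 15.9 & tb$bmi_kg_m2 <= 53.9))
  # composition
  p_t2d <- 154 / 497
  expect_lt(abs(mean(tb$cohort == "T2D") - p_t2d),
            3 * sqrt(p_t2d * (1 - p_t2d) / 5000))
  p_im <- 229 / 497
  expect_lt(abs(mean(tb$test_type == "IM-IVGTT") - p_im),
            3 * sqrt(p_im * (1 - p_im) / 5000))
  # dose is 0.3 g/kg in mmol
  expect_equal(tb$dose_mmol, dose_to_mmol(0.3, tb$weight_kg))
  # determinism
  expect_identical(tb, generate_covariates(spec))
})

test_that("missing covariates are imputed by the stated rules", {
  tb <- data.frame(subject_id = sprintf("I%02d", 1:8),
                   study = c(1, 1, 1, 1, 2, 2, 2, 2),
                   sex = c("F", "M", NA, "M", "F", "F", NA, "M"),
                   age_yr = c(30, 40, NA, 50, 60, NA, 62, 58),
                   weight_kg = c(70, 80, 90, NA, NA, NA, 75, 60),
                   height_cm = c(170, 175, NA, 172, NA, NA, NA, 160),
                   bmi_kg_m2 = c(NA, 26.1, 28, 30, 31, 29, NA, NA))
  out <- impute_missing(tb, seed = 3)
  expect_false(anyNA(out[c("age_yr", "weight_kg", "height_cm", "bmi_kg_m2")]))
  # group-mean age for I03 (study 1: 30, 40, 50)
  expect_equal(out$age_yr[3], 40)
  # algebraic completion where two of three are present
  expect_equal(out$bmi_kg_m2[1], 70 / 1.70^2)
  expect_equal(out$height_cm[3], 100 * sqrt(90 / 28))
  expect_equal(out$weight_kg[4], 30 * 1.72^2)
  # surrogate path (only BMI present) keeps BMI and derives weight from height
  expect_equal(out$weight_kg[5], out$bmi_kg_m2[5] * (out$height_cm[5] / 100)^2)
  # fully observed rows unchanged
  expect_equal(out$weight_kg[c(1, 2, 3, 8)], c(70, 80, 90, 60))
  # sex filled from observed group proportions
  expect_true(all(out$sex %in% c("F", "M")))
  # deterministic under the seed
  expect_identical(out, impute_missing(tb, seed = 3))
  # unfillable gap errors with subject named
  bad <- data.frame(subject_id = "Z1", sex = "F", age_yr = 30,
                    weight_kg = NA_real_, height_cm = NA_real_,
                    bmi_kg_m2 = NA_real_)
  expect_error(impute_missing(bad, seed = 1), class = "mmpop_data_error")
})

test_that("insulin profiles start at basal, decay back, and IM splits at 20 min", {
  for (seed in 1:10) {
    f <- insulin_profile("ND", "IVGTT", 75, 240, seed = seed)
    expect_equal(f$concentrations[1], f$Ibasal)
    expect_true(all(f$concentrations >= f$Ibasal / 2))
    # returns to within 10% of basal by the final knot
    expect_lt(abs(f$concentrations[length(f$concentrations)] - f$Ibasal) /
                f$Ibasal, 0.10)
    f2 <- insulin_profile("T2D", "IVGTT", 90, 180, seed = seed)
    expect_lt(abs(f2$concentrations[length(f2$concentrations)] - f2$Ibasal) /
                f2$Ibasal, 0.10)
    # IM adds signal only after the 20-min infusion
    fa <- insulin_profile("ND", "IVGTT", 75, 240, seed = seed)
    fb <- insulin_profile("ND", "IM-IVGTT", 75, 240, seed = seed)
    tt <- seq(0, 20, by = 0.5)
    expect_equal(interpolate_insulin(fa, tt), interpolate_insulin(fb, tt))
    expect_gt(interpolate_insulin(fb, 25), interpolate_insulin(fa, 25))
  }
})

test_that("sampling schedules respect the stated design ranges", {
  for (seed in 1:50) {
    s1 <- sampling_schedule("IVGTT", seed = seed)
    expect_true(length(s1) >= 12 && length(s1) <= 30)
    expect_true(max(s1) >= 180 && max(s1) <= 360)
    expect_true(all(diff(s1) > 0))
    expect_equal(s1[1], 0)
    s2 <- sampling_schedule("IM-IVGTT", seed = seed)
    expect_true(length(s2) >= 12 && length(s2) <= 22)
    expect_true(max(s2) >= 180 && max(s2) <= 240)
    # dense early sampling
    expect_gte(sum(s2 <= 30), 5)
  }
})

test_that("trial observations carry the configured proportional noise", {
  pop <- pop_base_model()
  spec0 <- cohort_spec(n_subjects = 5, true_pop = population_params(
    pop$mu_log, pop$Sigma_log, list(), 1e-9), seed = 21,
    basal_assay_cv = c(glucose = 0, insulin = 0))
  tr0 <- simulate_trial(spec0)
  # sigma ~ 0: observations equal the model solution at the true parameters
  s <- tr0$subjects[[1]]
  th <- unlist(tr0$truth[1, mmpop:::MM_PARS])
  f <- simulate_glucose(mm_params(th[1], th[2], th[3], th[4]), s$dose,
                        s$Gbasal, s$Ibasal, s$forcing, s$obs_times)
  expect_equal(s$obs_glucose, f, tolerance = 1e-5)

  # empirical CV of the relative residuals matches sigma
  spec <- cohort_spec(n_subjects = 250, true_pop = pop_base_model(), seed = 22,
                      basal_assay_cv = c(glucose = 0, insulin = 0))
  tr <- simulate_trial(spec)
  rel <- unlist(lapply(seq_along(tr$subjects), function(i) {
    s <- tr$subjects[[i]]
    th <- unlist(tr$truth[i, mmpop:::MM_PARS])
    f <- simulate_glucose(mm_params(th[1], th[2], th[3], th[4]), s$dose,
                          s$Gbasal, s$Ibasal, s$forcing, s$obs_times)
    (s$obs_glucose - f) / f
  }))
  expect_gt(length(rel), 4000)
  expect_equal(sd(rel), 0.0706, tolerance = 0.05)
  expect_lt(abs(mean(rel)), 3 * sd(rel) / sqrt(length(rel)))
})

test_that("trial generation is deterministic and never leaks truth", {
  spec <- cohort_spec(n_subjects = 4, seed = 31)
  a <- simulate_trial(spec)
  b <- simulate_trial(spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth, b$truth)
  # the subject records contain no true parameter fields
  expect_false(any(mmpop:::MM_PARS %in% names(a$subjects[[1]])))
  expect_false(any(mmpop:::MM_PARS %in% names(a$subjects[[1]]$covariates)))
})
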
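# Covariate screening on empirical conditional means, forward selection
# with LRT gating, and the structured report.

fake_fit <- function(B) {
  structure(list(conditional_mean_log = B,
                 subject_ids = rownames(B)), class = "mm_fit")
}

test_that("screening ranks a strong true association first", {
  set.seed(12)
  n <- 120
  bmi <- exp(rnorm(n, log(27), 0.2))
  B <- cbind(GEZI = rnorm(n, log(0.018), 0.3),
             SI = log(3.6e-5) - 2.14 * log(bmi / 25.3) + rnorm(n, 0, 0.4),
             p2 = rnorm(n, log(0.04), 0.3),
             V = rnorm(n, log(12), 0.2))
  rownames(B) <- sprintf("F%03d", 1:n)
  tb <- data.frame(subject_id = rownames(B), bmi_kg_m2 = bmi,
                   age_yr = rnorm(n, 40, 15),
                   T2D = rbinom(n, 1, 0.3))
  sc <- ebe_screen(fake_fit(B), tb)
  si_rows <- sc[sc$parameter == "SI", ]
  expect_equal(si_rows$covariate[1], "bmi_kg_m2")
  expect_lt(si_rows$p_value[1], 1e-6)
  expect_equal(si_rows$kind_suggested[1], "power_centered")
  # a categorical candidate is handled by a rank-sum comparison
  expect_true("T2D" %in% sc$covariate)
  # constant covariates are skipped with a warning
  tb$flat <- 1
  expect_warning(sc2 <- ebe_screen(fake_fit(B), tb), "constant")
  expect_false("flat" %in% sc2$covariate)
})

test_that("null covariates screen near-uniformly", {
  set.seed(21)
  n <- 150
  B <- cbind(GEZI = rnorm(n), SI = rnorm(n), p2 = rnorm(n), V = rnorm(n))
  rownames(B) <- sprintf("N%03d", 1:n)
  ps <- replicate(20, {
    tb <- data.frame(subject_id = rownames(B), noise = rnorm(n))
    sc <- ebe_screen(fake_fit(B), tb)
    sc$p_value[sc$parameter == "SI"]
  })
  expect_gte(mean(ps > 0.05), 0.7)
  expect_gt(min(ps), 1e-4)
})

test_that("forward selection returns the base model for an empty candidate list", {
  ds <- make_dataset(n = 10, sigma = 0.05)
  st <- quick_settings(seed = 3)
  base <- suppressWarnings(em_fit(ds, settings = st))
  out <- forward_select(ds, list(), settings = st, base_fit = base)
  expect_identical(out$fit, base)
  expect_equal(length(out$spec), 0)
})

test_that("forward selection retains a strong true effect and orders by priority", {
  # cohort with a large T2D effect on GEZI and none elsewhere
  set.seed(41)
  pop <- population_params(
    log(c(GEZI = 0.0178, SI = 3.59e-5, p2 = 0.0425, V = 12.4)),
    mmpop:::sigma_from_cv(c(30, 40, 30, 20), 0),
    list(covariate_effect("GEZI", "T2D", "proportional_shift",
                          coefficient = -0.5)),
    sigma_prop = 0.05)
  ds <- lapply(1:30, function(i) {
    t2d <- as.numeric(i <= 15)
    th <- sample_individual(pop, list(T2D = t2d))
    make_subject(sprintf("W%02d", i), params = th, sigma = 0.05,
                 seed = 700 + i, covariates = list(T2D = t2d, IM = 0))
  })
  st <- fit_settings(n_importance_samples = 60, max_iterations = 12, seed = 5)
  cands <- list(
    covariate_effect("GEZI", "T2D", "proportional_shift"),
    covariate_effect("SI", "T2D", "proportional_shift"))
  out <- suppressWarnings(
    forward_select(ds, cands, settings = st, rse_threshold = Inf))
  # SI candidates are tested before GEZI candidates
  expect_equal(out$steps$effect[1], "SI~T2D")
  # the T2D signal is picked up (GEZI and SI shifts are partly exchangeable
  # within the glucose likelihood, so attribution between them is not asserted)
  kept <- vapply(out$spec, mmpop:::effect_label, "")
  expect_gt(length(kept), 0)
  expect_true(all(vapply(out$spec, `[[`, 0, "coefficient") < 0))
  # nesting: final -2LL does not exceed base -2LL beyond MC noise
  expect_lt(as.numeric(out$fit$minus2LL),
            as.numeric(out$base_fit$minus2LL) + 10)

  # without a competing candidate the true effect is retained with the
  # right sign and magnitude
  solo <- suppressWarnings(forward_select(
    ds, list(covariate_effect("GEZI", "T2D", "proportional_shift")),
    settings = st, rse_threshold = Inf, base_fit = out$base_fit))
  expect_equal(solo$steps$decision, "retained")
  expect_lt(solo$steps$p_value, 0.01)
  expect_lt(solo$spec[[1]]$coefficient, -0.2)
})

test_that("the model report is self-consistent and JSON round-trips", {
  ds <- lapply(1:10, function(i) {
    make_subject(sprintf("J%02d", i), sigma = 0.05, seed = 800 + i,
                 covariates = list(T2D = as.numeric(i %% 2 == 0), IM = 0))
  })
  st <- quick_settings(seed = 13)
  base <- suppressWarnings(em_fit(ds, settings = st))
  fin <- suppressWarnings(em_fit(
    ds, spec = list(covariate_effect("GEZI", "T2D", "proportional_shift")),
    init = NULL, settings = st))
  rep <- final_model_report(fin, base)
  expect_equal(unlist(rep$final$typical_values),
               typical_values(fin$pop), tolerance = 1e-12)
  expect_equal(rep$base$minus2LL, as.numeric(base$minus2LL))
  expect_equal(rep$lrt$df, 1)

  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(rep), tmp, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$final$minus2LL, as.numeric(fin$minus2LL))
  expect_equal(unlist(back$final$typical_values),
               typical_values(fin$pop), tolerance = 1e-12)
})
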
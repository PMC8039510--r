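# Virtual IVGTT / IM-IVGTT trial generator.
#
# Emulates the pooled-study design: cohort composition, covariate
# distributions, sampling schedules, per-subject insulin forcing, true
# parameters drawn from the log-normal hierarchy, and proportional
# measurement noise. Insulin profile shapes are synthetic (parameterized
# bi-exponential responses) since no measured profiles are available; they
# are documented so measured profiles can be substituted.

#' Cohort generation settings
#'
#' Defaults reproduce the pooled-study composition: 497 subjects with
#' 154/497 T2D, 229/497 insulin-modified tests, sex split 239 F / 217 M /
#' 41 unrecorded, age 41.4 +/- 16.9 yr within 9.7..86, height 169 +/- 10.1 cm
#' within 130..196, pooled BMI 28.0 +/- 6.76 kg/m2 within 15.9..53.9 (drawn
#' per cohort: heavier T2D, with the mixture matching the pooled mean).
#' Weight is derived as BMI * height^2 so the anthropometry is internally
#' consistent.
#'
#' @param n_subjects Number of subjects.
#' @param frac_T2D,frac_IM Expected fractions of T2D subjects and of
#'   insulin-modified tests.
#' @param sex_proportions Named proportions for F, M and NA.
#' @param age,height Truncated-normal settings `c(mean, sd, min, max)`.
#' @param bmi_nd,bmi_t2d Per-cohort truncated-normal BMI settings.
#' @param gbasal_nd,gbasal_t2d Per-cohort basal glucose settings (mmol/L).
#' @param insulin Per-cohort insulin-profile settings; see
#'   [insulin_profile()].
#' @param true_pop [population_params()] from which true individual
#'   parameters are drawn.
#' @param dose_g_per_kg Glucose dose (0.3 g/kg standard).
#' @param basal_assay_cv Assay-level proportional noise applied to the
#'   "measured" basal glucose and insulin handed to the fitter (the dynamic
#'   proportional error additionally covers model misspecification, hence is
#'   larger).
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 497,
                        frac_T2D = 154 / 497,
                        frac_IM = 229 / 497,
                        sex_proportions = c(F = 239, M = 217, "NA" = 41) / 497,
                        age = c(mean = 41.4, sd = 16.9, min = 9.7, max = 86),
                        height = c(mean = 169, sd = 10.1, min = 130, max = 196),
                        bmi_nd = c(mean = 26.6, sd = 6.3, min = 15.9, max = 53.9),
                        bmi_t2d = c(mean = 31.0, sd = 6.3, min = 15.9, max = 53.9),
                        gbasal_nd = c(mean = 5.1, sd = 0.4, min = 3.8, max = 7.0),
                        gbasal_t2d = c(mean = 8.5, sd = 1.5, min = 5.0, max = 14.0),
                        insulin = default_insulin_settings(),
                        true_pop = pop_final_model(),
                        dose_g_per_kg = 0.3,
                        basal_assay_cv = c(glucose = 0.02, insulin = 0.05),
                        seed = 1L) {
  if (frac_T2D < 0 || frac_T2D > 1 || frac_IM < 0 || frac_IM > 1)
    abort_invalid("fractions must lie in [0, 1]")
  for (d in list(age, height, bmi_nd, bmi_t2d, gbasal_nd, gbasal_t2d)) {
    if (d[["min"]] >= d[["max"]] || d[["sd"]] <= 0)
      abort_config("inconsistent truncated-normal settings")
    if (d[["mean"]] <= d[["min"]] || d[["mean"]] >= d[["max"]])
      abort_config("target mean outside truncation bounds")
  }
  stopifnot(inherits(true_pop, "population_params"))
  structure(list(n_subjects = as.integer(n_subjects), frac_T2D = frac_T2D,
                 frac_IM = frac_IM,
                 sex_proportions = sex_proportions / sum(sex_proportions),
                 age = age, height = height, bmi_nd = bmi_nd, bmi_t2d = bmi_t2d,
                 gbasal_nd = gbasal_nd, gbasal_t2d = gbasal_t2d,
                 insulin = insulin, true_pop = true_pop,
                 dose_g_per_kg = dose_g_per_kg,
                 basal_assay_cv = basal_assay_cv, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default synthetic insulin-profile settings
#'
#' ND subjects: basal ~45 pmol/L, brisk first-phase peak (~500 pmol/L above
#' basal within 3-5 min) and a moderate slower second phase. T2D subjects:
#' marked fasting hyperinsulinemia (~220 pmol/L), a blunted first phase and
#' a large, sustained second phase, reflecting the elevated insulin
#' exposure that insulin-resistant cohorts show during an IVGTT. Second
#' phases are amplitude-capped so every profile decays back to near basal
#' by the end of the test. All amplitudes carry log-normal between-subject
#' variability.
#'
#' @return Nested list of per-cohort profile parameters.
#' @export
default_insulin_settings <- function() {
  list(
    ND = list(Ib = c(mean = 45, cv = 0.35),
              A1 = c(mean = 500, cv = 0.50), rise1 = 1.2, decay1 = 12,
              A2 = c(mean = 120, cv = 0.50), rise2 = 15, decay2 = 45),
    T2D = list(Ib = c(mean = 220, cv = 0.35),
               A1 = c(mean = 150, cv = 0.55), rise1 = 1.2, decay1 = 10,
               A2 = c(mean = 500, cv = 0.50), rise2 = 20, decay2 = 45),
    IM = list(amp_per_004U = 2000, cv = 0.30, onset = 20, rise = 1.5,
              decay = 10, dose_U_kg = c(min = 0.03, max = 0.05))
  )
}

#' Generate a covariate table
#'
#' Truncated-normal draws whose truncated means match the targets; BMI drawn
#' per cohort; weight derived as `BMI * (height/100)^2`; the 0.3 g/kg dose
#' converted to mmol.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed (defaults to the spec's).
#' @return Data frame: subject_id, cohort, test_type, sex, age_yr, height_cm,
#'   bmi_kg_m2, weight_kg, dose_mmol.
#' @export
generate_covariates <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  set.seed(derive_seed(seed, "covariates"))
  cohort <- ifelse(runif(n) < spec$frac_T2D, "T2D", "ND")
  test_type <- ifelse(runif(n) < spec$frac_IM, "IM-IVGTT", "IVGTT")
  sex <- sample(names(spec$sex_proportions), n, replace = TRUE,
                prob = spec$sex_proportions)
  sex[sex == "NA"] <- NA_character_
  age <- rtnorm_matched(n, spec$age[["mean"]], spec$age[["sd"]],
                        spec$age[["min"]], spec$age[["max"]])
  height <- rtnorm_matched(n, spec$height[["mean"]], spec$height[["sd"]],
                           spec$height[["min"]], spec$height[["max"]])
  bmi <- numeric(n)
  nd <- cohort == "ND"
  if (any(nd))
    bmi[nd] <- rtnorm_matched(sum(nd), spec$bmi_nd[["mean"]], spec$bmi_nd[["sd"]],
                              spec$bmi_nd[["min"]], spec$bmi_nd[["max"]])
  if (any(!nd))
    bmi[!nd] <- rtnorm_matched(sum(!nd), spec$bmi_t2d[["mean"]], spec$bmi_t2d[["sd"]],
                               spec$bmi_t2d[["min"]], spec$bmi_t2d[["max"]])
  weight <- bmi * (height / 100)^2
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             cohort = cohort, test_type = test_type, sex = sex,
             age_yr = age, height_cm = height, bmi_kg_m2 = bmi,
             weight_kg = weight,
             dose_mmol = dose_to_mmol(spec$dose_g_per_kg, weight))
}

#' Impute missing covariate values
#'
#' Rules follow common pooled-study practice: missing age/weight/height/BMI
#' with group information available are assigned the group mean; missing sex
#' is randomly assigned from the observed group proportions; when two of
#' (weight, height, BMI) are present the third is completed algebraically
#' (`height = 100*sqrt(weight/BMI)`); when only BMI is present, height is
#' drawn from a sex-specific normal surrogate (F 162 +/- 7 cm, M 176 +/- 7
#' cm) and weight back-calculated from BMI.
#'
#' @param table Covariate data frame (columns as [generate_covariates()];
#'   an optional `study` column defines imputation groups).
#' @param seed Seed for the random assignments.
#' @param height_surrogate Sex-specific normal settings used when both
#'   height and weight are missing.
#' @return Completed data frame.
#' @export
impute_missing <- function(table, seed = 1L,
                           height_surrogate = list(F = c(162, 7), M = c(176, 7))) {
  set.seed(derive_seed(seed, "impute"))
  tb <- table
  grp <- if ("study" %in% names(tb)) as.character(tb$study) else rep("all", nrow(tb))
  grp_mean <- function(x, g) {
    m <- tapply(x, g, function(v) mean(v, na.rm = TRUE))
    as.numeric(m[g])
  }
  if ("age_yr" %in% names(tb) && anyNA(tb$age_yr)) {
    fill <- grp_mean(tb$age_yr, grp)
    bad <- is.na(tb$age_yr) & is.na(fill)
    if (any(bad))
      abort_data(paste0("cannot impute age_yr for subject(s) ",
                        paste(tb$subject_id[bad], collapse = ", "),
                        " (no observed values in group)"))
    tb$age_yr[is.na(tb$age_yr)] <- fill[is.na(tb$age_yr)]
  }
  if ("sex" %in% names(tb) && anyNA(tb$sex)) {
    for (g in unique(grp)) {
      in_g <- grp == g & is.na(tb$sex)
      if (!any(in_g)) next
      obs <- tb$sex[grp == g & !is.na(tb$sex)]
      if (length(obs) == 0) next  # no proportion reported: leave NA
      tb$sex[in_g] <- sample(obs, sum(in_g), replace = TRUE)
    }
  }
  w <- tb$weight_kg; h <- tb$height_cm; b <- tb$bmi_kg_m2
  for (i in seq_len(nrow(tb))) {
    miss <- c(w = is.na(w[i]), h = is.na(h[i]), b = is.na(b[i]))
    if (!any(miss)) next
    if (sum(miss) == 1) {
      if (miss["h"]) h[i] <- 100 * sqrt(w[i] / b[i])
      else if (miss["w"]) w[i] <- b[i] * (h[i] / 100)^2
      else b[i] <- w[i] / (h[i] / 100)^2
    } else if (sum(miss) == 2 && !miss["b"]) {
      sx <- tb$sex[i]
      if (is.na(sx) || !sx %in% names(height_surrogate))
        sx <- sample(names(height_surrogate), 1)
      hs <- height_surrogate[[sx]]
      h[i] <- rnorm(1, hs[1], hs[2])
      w[i] <- b[i] * (h[i] / 100)^2
    } else if (sum(miss) == 2 && !miss["w"]) {
      fill_b <- grp_mean(b, grp)[i]
      if (is.na(fill_b))
        abort_data(sprintf("cannot impute height/bmi for subject %s", tb$subject_id[i]))
      b[i] <- fill_b
      h[i] <- 100 * sqrt(w[i] / b[i])
    } else {
      fw <- grp_mean(w, grp)[i]; fh <- grp_mean(h, grp)[i]; fb <- grp_mean(b, grp)[i]
      if (is.na(fw) && is.na(fh) && is.na(fb))
        abort_data(sprintf(
          "cannot impute anthropometry for subject %s (fields weight_kg/height_cm/bmi_kg_m2)",
          tb$subject_id[i]))
      if (is.na(w[i]) && !is.na(fw)) w[i] <- fw
      if (is.na(h[i]) && !is.na(fh)) h[i] <- fh
      if (is.na(b[i]) && !is.na(fb)) b[i] <- fb
      miss2 <- c(is.na(w[i]), is.na(h[i]), is.na(b[i]))
      if (sum(miss2) == 1) {
        if (is.na(h[i])) h[i] <- 100 * sqrt(w[i] / b[i])
        else if (is.na(w[i])) w[i] <- b[i] * (h[i] / 100)^2
        else b[i] <- w[i] / (h[i] / 100)^2
      } else if (any(miss2)) {
        abort_data(sprintf("cannot complete anthropometry for subject %s",
                           tb$subject_id[i]))
      }
    }
  }
  tb$weight_kg <- w; tb$height_cm <- h; tb$bmi_kg_m2 <- b
  tb
}

knot_template <- function(duration) {
  kn <- c(0, 2, 4, 6, 8, 10, 12, 15, 20, 22, 25, 30, 40, 50, 60, 80, 100,
          120, 150, 180, 210, 240, 270, 300, 330, 360)
  sort(unique(c(kn[kn < duration], duration)))
}

#' Synthetic insulin forcing profile for one subject
#'
#' Basal level plus a fast first-phase peak (3-5 min) and a slower second
#' phase, both decaying exponentially toward basal; insulin-modified tests
#' add an exogenous-infusion response starting at 20 min. With the same
#' seed, the IVGTT and IM-IVGTT profiles of a subject are identical before
#' 20 min.
#'
#' @param cohort `"ND"` or `"T2D"`.
#' @param test_type `"IVGTT"` or `"IM-IVGTT"`.
#' @param weight Body weight in kg (scales the exogenous insulin dose).
#' @param duration Test duration in minutes (final knot).
#' @param seed Integer seed.
#' @param settings Profile settings, see [default_insulin_settings()].
#' @return An [insulin_forcing()] object.
#' @export
insulin_profile <- function(cohort, test_type, weight, duration, seed,
                            settings = default_insulin_settings()) {
  ps <- settings[[cohort]]
  if (is.null(ps)) abort_invalid(sprintf("unknown cohort '%s'", cohort))
  set.seed(derive_seed(seed, "insulin"))
  ln <- function(mean, cv) rlnorm(1, log(mean) - 0.5 * log(1 + cv^2),
                                  sqrt(log(1 + cv^2)))
  Ib <- ln(ps$Ib[["mean"]], ps$Ib[["cv"]])
  A1 <- ln(ps$A1[["mean"]], ps$A1[["cv"]])
  A2 <- ln(ps$A2[["mean"]], ps$A2[["cv"]])
  # structural guarantee that the endogenous response has returned to
  # within a few percent of basal by the end of the test, whatever the
  # amplitude draw
  tail2 <- (1 - exp(-duration / ps$rise2)) * exp(-duration / ps$decay2)
  if (tail2 > 0) A2 <- min(A2, 0.06 * Ib / tail2)
  im <- settings$IM
  dose_U <- runif(1, im$dose_U_kg[["min"]], im$dose_U_kg[["max"]])
  A_im <- im$amp_per_004U * (dose_U / 0.04) * (weight / 75) *
    ln(1, im$cv)
  tk <- knot_template(duration)
  ins <- Ib +
    A1 * (1 - exp(-tk / ps$rise1)) * exp(-tk / ps$decay1) +
    A2 * (1 - exp(-tk / ps$rise2)) * exp(-tk / ps$decay2)
  if (test_type == "IM-IVGTT") {
    td <- pmax(tk - im$onset, 0)
    ins <- ins + A_im * (1 - exp(-td / im$rise)) * exp(-td / im$decay)
  }
  insulin_forcing(tk, ins, Ibasal = Ib)
}

#' Draw a glucose sampling schedule
#'
#' IVGTT: duration 180-360 min with 12-30 samples; IM-IVGTT: duration
#' 180-240 min with 12-22 samples. Sampling is dense before 30 min and
#' sparse later; t = 0 and the endpoint are always included.
#'
#' @param test_type `"IVGTT"` or `"IM-IVGTT"`.
#' @param seed Integer seed.
#' @return Strictly increasing vector of observation times (minutes).
#' @export
sampling_schedule <- function(test_type = c("IVGTT", "IM-IVGTT"), seed = 1L) {
  test_type <- match.arg(test_type)
  set.seed(derive_seed(seed, "schedule"))
  template <- c(0, 2, 3, 4, 5, 6, 8, 10, 12, 15, 19, 22, 25, 30, 35, 40, 50,
                60, 70, 80, 90, 100, 110, 120, 140, 160, 180, 210, 240, 270,
                300, 330, 360)
  if (test_type == "IVGTT") {
    duration <- sample(c(180, 210, 240, 270, 300, 330, 360), 1)
    n <- sample(12:30, 1)
  } else {
    duration <- sample(c(180, 210, 240), 1)
    n <- sample(12:22, 1)
  }
  avail <- template[template <= duration]
  n <- min(n, length(avail))
  early <- setdiff(avail[avail <= 30], c(0, duration))
  late <- setdiff(avail[avail > 30], c(0, duration))
  n_rem <- n - 2
  n_early <- min(length(early), max(n_rem - length(late), round(0.55 * n_rem)))
  n_late <- min(length(late), n_rem - n_early)
  n_early <- n_rem - n_late
  pick <- function(x, k) x[sample.int(length(x), k)]
  sort(c(0, duration, pick(early, n_early),
         if (n_late > 0) pick(late, n_late)))
}

#' Simulate a complete virtual trial
#'
#' Per subject: covariates, true parameters drawn from the hierarchy, the
#' 0.3 g/kg dose, a synthetic insulin profile, the noiseless model solution
#' at the drawn schedule, and observations perturbed by proportional noise
#' `y = f * (1 + sigma * eps)` floored at 0.1 mmol/L. Basal glucose and
#' insulin are stored as "measured" values (truth plus proportional
#' measurement noise). True parameters are kept separately from the subject
#' records.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed (defaults to the spec's).
#' @return Object of class `trial_dataset`: list with `subjects` (list of
#'   [subject_data()]), `truth` (data frame of true parameters) and
#'   `covariates` (the covariate table).
#' @export
simulate_trial <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  covs <- generate_covariates(spec, seed = seed)
  n <- nrow(covs)
  sigma <- spec$true_pop$sigma_prop
  subjects <- vector("list", n)
  truth <- matrix(NA_real_, n, 4, dimnames = list(covs$subject_id, MM_PARS))
  for (i in seq_len(n)) {
    id <- covs$subject_id[i]
    cohort <- covs$cohort[i]
    covrow <- list(age_yr = covs$age_yr[i], weight_kg = covs$weight_kg[i],
                   height_cm = covs$height_cm[i], bmi_kg_m2 = covs$bmi_kg_m2[i],
                   sex = covs$sex[i],
                   T2D = as.numeric(cohort == "T2D"),
                   IM = as.numeric(covs$test_type[i] == "IM-IVGTT"))
    s_seed <- derive_seed(seed, id)
    sched <- sampling_schedule(covs$test_type[i], seed = derive_seed(s_seed, "sched"))
    duration <- max(sched)
    forcing <- insulin_profile(cohort, covs$test_type[i], covs$weight_kg[i],
                               duration, seed = derive_seed(s_seed, "ins"),
                               settings = spec$insulin)
    gb_spec <- if (cohort == "ND") spec$gbasal_nd else spec$gbasal_t2d
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      set.seed(derive_seed(s_seed, "params", attempt))
      Gb_true <- rtnorm_matched(1, gb_spec[["mean"]], gb_spec[["sd"]],
                                gb_spec[["min"]], gb_spec[["max"]])
      th <- sample_individual(spec$true_pop, covrow)
      f <- tryCatch(
        simulate_glucose(th, covs$dose_mmol[i], Gb_true, forcing$Ibasal,
                         forcing, sched),
        error = function(e) NULL)
      if (!is.null(f) && all(is.finite(f)) && all(f > 0)) break
      if (attempt >= 3L)
        abort_numerical(sprintf("could not simulate subject %s in 3 attempts", id))
    }
    set.seed(derive_seed(s_seed, "noise"))
    y <- pmax(f * (1 + sigma * rnorm(length(f))), 0.1)
    Gb_meas <- max(Gb_true * (1 + spec$basal_assay_cv[["glucose"]] * rnorm(1)), 0.5)
    Ib_meas <- forcing$Ibasal * (1 + spec$basal_assay_cv[["insulin"]] * rnorm(1))
    subjects[[i]] <- subject_data(
      subject_id = id, test_type = covs$test_type[i],
      dose = covs$dose_mmol[i], obs_times = sched, obs_glucose = y,
      forcing = forcing, Gbasal = Gb_meas, Ibasal = Ib_meas,
      covariates = covrow)
    truth[i, ] <- unclass(th)
  }
  structure(list(subjects = subjects,
                 truth = data.frame(subject_id = covs$subject_id, truth,
                                    row.names = NULL),
                 covariates = covs, spec = spec, seed = seed),
            class = "trial_dataset")
}

#' @importFrom stats rlnorm
NULL
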
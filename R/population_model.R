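# Stage-2 hierarchy: log-normal population distribution of the minimal-model
# parameters with a declarative covariate model.
#
# logtheta_i ~ N(mu_log + shift_i(covariates), Sigma_log), where shifts are
# log(1 + phi) for proportional (categorical) effects and
# exponent * log(cov/reference) for power effects centered at the reference.

#' Declare one covariate effect on one parameter
#'
#' Two kinds are supported, matching the forms in which covariate models are
#' usually reported: `power_centered`, `TV * (cov/reference)^coefficient`,
#' for continuous covariates centered at a reference (study median); and
#' `proportional_shift`, `TV * (1 + coefficient * indicator)`, for 0/1
#' categorical covariates.
#'
#' @param parameter One of `"GEZI"`, `"SI"`, `"p2"`, `"V"`.
#' @param covariate Covariate name (must be present in the covariate table,
#'   e.g. `"bmi_kg_m2"`, `"weight_kg"`, `"T2D"`, `"IM"`).
#' @param kind `"power_centered"` or `"proportional_shift"`.
#' @param reference Centering value for power effects (ignored, and defaulted
#'   to 0, for proportional shifts).
#' @param coefficient Exponent (power) or fractional shift (proportional;
#'   must stay above -1 so the multiplier is positive).
#' @return Object of class `covariate_effect`.
#' @export
covariate_effect <- function(parameter, covariate,
                             kind = c("power_centered", "proportional_shift"),
                             reference = NA_real_, coefficient = 0) {
  kind <- match.arg(kind)
  if (!parameter %in% MM_PARS)
    abort_invalid(sprintf("unknown parameter '%s'", parameter))
  if (kind == "proportional_shift" && coefficient <= -1)
    abort_invalid("proportional_shift coefficient must be > -1")
  if (kind == "power_centered" && (!is.finite(reference) || reference <= 0))
    abort_invalid("power_centered effects need a positive reference value")
  structure(list(parameter = parameter, covariate = covariate, kind = kind,
                 reference = if (kind == "power_centered") reference else 0,
                 coefficient = coefficient),
            class = "covariate_effect")
}

effect_label <- function(e) paste0(e$parameter, "~", e$covariate)

#' Population parameter set
#'
#' @param mu_log Named 4-vector of log typical values (order GEZI, SI, p2, V)
#'   at the reference covariates.
#' @param Sigma_log 4x4 symmetric positive-definite covariance of the random
#'   effects on the log scale.
#' @param effects List of [covariate_effect()] objects (may be empty).
#' @param sigma_prop Proportional residual-error scale (SD of the relative
#'   residual), > 0.
#' @return Object of class `population_params`.
#' @export
population_params <- function(mu_log, Sigma_log, effects = list(), sigma_prop) {
  mu_log <- setNames(as.numeric(mu_log), MM_PARS)
  Sigma_log <- as.matrix(Sigma_log)
  dimnames(Sigma_log) <- list(MM_PARS, MM_PARS)
  if (!is_spd(Sigma_log)) abort_invalid("Sigma_log must be symmetric positive definite")
  if (!is.finite(sigma_prop) || sigma_prop <= 0)
    abort_invalid("sigma_prop must be > 0")
  stopifnot(all(vapply(effects, inherits, logical(1), "covariate_effect")))
  structure(list(mu_log = mu_log, Sigma_log = Sigma_log,
                 effects = effects, sigma_prop = as.numeric(sigma_prop)),
            class = "population_params")
}

#' Typical values (natural scale)
#'
#' @param pop A [population_params()] object.
#' @return Named vector `exp(mu_log)`.
#' @export
typical_values <- function(pop) {
  stopifnot(inherits(pop, "population_params"))
  exp(pop$mu_log)
}

#' Inter-individual variability as CV%
#'
#' `100 * sqrt(diag(Sigma))`, the usual log-normal CV% approximation.
#'
#' @param Sigma 4x4 SPD log-scale covariance (or a [population_params()]).
#' @return Named vector of CV percentages.
#' @export
iiv_cv <- function(Sigma) {
  if (inherits(Sigma, "population_params")) Sigma <- Sigma$Sigma_log
  if (!is_spd(Sigma, tol = -1e-12)) abort_invalid("Sigma must be symmetric positive semi-definite")
  setNames(100 * sqrt(diag(Sigma)), colnames(Sigma))
}

# log-scale covariate contribution for one subject: named 4-vector of shifts
covariate_log_shift <- function(effects, covariates) {
  shift <- setNames(numeric(4), MM_PARS)
  for (e in effects) {
    v <- covariates[[e$covariate]]
    if (is.null(v) || length(v) != 1 || is.na(v))
      abort_config(sprintf("covariate '%s' required by the model is missing", e$covariate))
    v <- as.numeric(v)
    shift[e$parameter] <- shift[e$parameter] +
      if (e$kind == "power_centered") {
        if (v <= 0) abort_invalid(sprintf("power-model covariate '%s' must be positive", e$covariate))
        e$coefficient * log(v / e$reference)
      } else {
        log1p(e$coefficient) * v
      }
  }
  shift
}

#' Subject-level typical values under the covariate model
#'
#' Evaluates `TV * prod(1 + phi*indicator) * prod((cov/ref)^exponent)` for a
#' single subject.
#'
#' @param pop A [population_params()] object.
#' @param covariates Named list or one-row data.frame of covariate values.
#' @return Named vector of subject-level typical values (natural scale).
#' @export
evaluate_covariate_model <- function(pop, covariates) {
  exp(individual_mean_log(pop, covariates))
}

#' Log-scale subject-level population mean
#'
#' `mu_log` plus the covariate shifts; equals `mu_log` when every covariate
#' is at its reference.
#'
#' @inheritParams evaluate_covariate_model
#' @return Named 4-vector on the log scale.
#' @export
individual_mean_log <- function(pop, covariates) {
  stopifnot(inherits(pop, "population_params"))
  pop$mu_log + covariate_log_shift(pop$effects, covariates)
}

#' Draw one individual parameter vector from the hierarchy
#'
#' Exponential of a multivariate-normal draw centered at the subject-level
#' log mean with covariance `Sigma_log`. Uses the current R RNG state; seed
#' with `set.seed()` for reproducibility.
#'
#' @inheritParams evaluate_covariate_model
#' @param n Number of draws.
#' @return For `n = 1` an [mm_params()] vector; otherwise an `n x 4` matrix.
#' @export
sample_individual <- function(pop, covariates = list(), n = 1) {
  m <- individual_mean_log(pop, covariates)
  L <- chol(pop$Sigma_log)
  Z <- matrix(rnorm(4 * n), n, 4)
  th <- exp(sweep(Z %*% L, 2, m, "+"))
  colnames(th) <- MM_PARS
  if (n == 1) mm_params(th[1, 1], th[1, 2], th[1, 3], th[1, 4]) else th
}

#' Absolute parameter spread from a CV%
#'
#' The +/- spread convention used when quoting, e.g., a typical value of
#' 0.021 1/min with variability of +/- 0.0097 1/min: `TV * cv/100`.
#'
#' @param TV Typical value (natural scale), > 0.
#' @param cv_percent CV percentage, >= 0.
#' @return Spread in the units of `TV`.
#' @export
approx_param_sd <- function(TV, cv_percent) {
  if (any(TV <= 0)) abort_invalid("TV must be > 0")
  if (any(cv_percent < 0)) abort_invalid("cv_percent must be >= 0")
  TV * cv_percent / 100
}

# build Sigma from IIV CV% and a GEZI-p2 correlation
sigma_from_cv <- function(cv_percent, r_gezi_p2 = 0) {
  s <- cv_percent / 100
  S <- diag(s^2)
  dimnames(S) <- list(MM_PARS, MM_PARS)
  S["GEZI", "p2"] <- S["p2", "GEZI"] <- r_gezi_p2 * s[1] * s[3]
  S
}

#' Reported base-model population parameters (no covariates)
#'
#' Typical values 0.0178 1/min (GEZI), 3.59e-5 1/min per pmol/L (SI),
#' 0.0425 1/min (p2), 12.4 L (V); IIV 50.9/113/44.0/34.4 CV%; proportional
#' error 0.0706; GEZI-p2 log-scale correlation 0.77.
#'
#' @return A [population_params()] object.
#' @export
pop_base_model <- function() {
  population_params(
    mu_log = log(c(GEZI = 0.0178, SI = 3.59e-5, p2 = 0.0425, V = 12.4)),
    Sigma_log = sigma_from_cv(c(50.9, 113, 44.0, 34.4), r_gezi_p2 = 0.77),
    effects = list(),
    sigma_prop = 0.0706
  )
}

#' Reported final covariate-model population parameters
#'
#' GEZI = 0.0210 * (1 - 0.473 * T2D);
#' SI = 6.26e-5 * (1 - 0.479 * T2D) * (1 - 0.345 * IM) * (BMI/25.3)^-2.14;
#' V = 12.0 * (weight/75)^0.865; p2 = 0.0420.
#' IIV 46.1/83.8/44.9/26.8 CV%, proportional error 0.0706.
#'
#' @return A [population_params()] object.
#' @export
pop_final_model <- function() {
  population_params(
    mu_log = log(c(GEZI = 0.0210, SI = 6.26e-5, p2 = 0.0420, V = 12.0)),
    Sigma_log = sigma_from_cv(c(46.1, 83.8, 44.9, 26.8), r_gezi_p2 = 0.77),
    effects = list(
      covariate_effect("GEZI", "T2D", "proportional_shift", coefficient = -0.473),
      covariate_effect("SI", "T2D", "proportional_shift", coefficient = -0.479),
      covariate_effect("SI", "bmi_kg_m2", "power_centered", reference = 25.3,
                       coefficient = -2.14),
      covariate_effect("SI", "IM", "proportional_shift", coefficient = -0.345),
      covariate_effect("V", "weight_kg", "power_centered", reference = 75,
                       coefficient = 0.865)
    ),
    sigma_prop = 0.0706
  )
}

#' @export
print.population_params <- function(x, ...) {
  tv <- typical_values(x)
  cv <- iiv_cv(x$Sigma_log)
  cat("<population_params>\n  typical values:",
      paste(sprintf("%s=%.4g", names(tv), tv), collapse = ", "),
      "\n  IIV CV%:",
      paste(sprintf("%s=%.3g", names(cv), cv), collapse = ", "),
      sprintf("\n  proportional error: %.4g\n", x$sigma_prop))
  if (length(x$effects)) {
    for (e in x$effects)
      cat(sprintf("  effect %s: %s coef %.4g (ref %.4g)\n",
                  effect_label(e), e$kind, e$coefficient, e$reference))
  }
  invisible(x)
}
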
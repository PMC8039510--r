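# Glucose minimal model: domain objects and forward simulation.
#
# Model (time in minutes from the glucose bolus):
#   dG/dt = -(GEZI + X(t)) G(t) + (GEZI + Xb) Gb,   G(0) = Gb + Dose/V
#   dX/dt = -p2 X(t) + p2 SI I(t),                  X(0) = SI Ib
# where I(t) linearly interpolates the measured insulin concentrations and
# Xb = SI * Ib is the basal remote insulin action.

MW_GLUCOSE <- 180.16  # g/mol

#' Insulin forcing function
#'
#' A piecewise-linear insulin concentration profile used to drive the remote
#' insulin-action compartment. Outside the measured range the profile is held
#' constant at the nearest measured value.
#'
#' @param times Sampling times in minutes, strictly increasing, at least two.
#' @param concentrations Insulin concentrations in pmol/L, non-negative.
#' @param Ibasal Basal insulin concentration in pmol/L.
#' @return An object of class `insulin_forcing`.
#' @export
insulin_forcing <- function(times, concentrations, Ibasal) {
  if (length(times) < 2) abort_invalid("insulin forcing needs at least 2 points")
  if (length(times) != length(concentrations))
    abort_invalid("times and concentrations must have equal length")
  if (any(diff(times) <= 0)) abort_invalid("forcing times must be strictly increasing")
  if (any(concentrations < 0)) abort_invalid("insulin concentrations must be >= 0")
  if (!is.finite(Ibasal) || Ibasal < 0) abort_invalid("Ibasal must be >= 0")
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 Ibasal = as.numeric(Ibasal)),
            class = "insulin_forcing")
}

#' Minimal-model parameter vector
#'
#' @param GEZI Glucose effectiveness at zero insulin (1/min).
#' @param SI Insulin sensitivity (1/min per pmol/L).
#' @param p2 Remote insulin-action rate constant (1/min).
#' @param V Glucose distribution volume (L).
#' @return Named numeric vector of class `mm_params`.
#' @export
mm_params <- function(GEZI, SI, p2, V) {
  th <- c(GEZI = unname(GEZI), SI = unname(SI), p2 = unname(p2), V = unname(V))
  if (any(!is.finite(th)) || any(th <= 0))
    abort_invalid("all minimal-model parameters must be strictly positive")
  structure(th, class = "mm_params")
}

#' One subject's IVGTT record
#'
#' @param subject_id Character id.
#' @param test_type `"IVGTT"` or `"IM-IVGTT"`.
#' @param dose Glucose dose in mmol given at time zero (may be `NA` until
#'   covariates are attached).
#' @param obs_times Glucose observation times in minutes, within 0..360.
#' @param obs_glucose Observed glucose in mmol/L, all positive.
#' @param forcing An [insulin_forcing()].
#' @param Gbasal Basal (end-point) glucose, mmol/L.
#' @param Ibasal Basal (end-point) insulin, pmol/L.
#' @param covariates Named list (age_yr, weight_kg, height_cm, bmi_kg_m2,
#'   sex, T2D, IM, ...); may be empty.
#' @return Object of class `subject_data`.
#' @export
subject_data <- function(subject_id, test_type = c("IVGTT", "IM-IVGTT"),
                         dose, obs_times, obs_glucose, forcing,
                         Gbasal, Ibasal, covariates = list()) {
  test_type <- match.arg(test_type)
  if (!is.na(dose) && dose <= 0) abort_invalid("dose must be > 0")
  if (length(obs_times) != length(obs_glucose))
    abort_invalid("obs_times and obs_glucose must have equal length")
  if (any(obs_times < 0 | obs_times > 360))
    abort_invalid("observation times must lie within [0, 360] minutes")
  if (any(diff(obs_times) <= 0))
    abort_invalid("observation times must be strictly increasing")
  if (any(obs_glucose <= 0)) abort_invalid("glucose observations must be > 0")
  if (!is.finite(Gbasal) || Gbasal <= 0) abort_invalid("Gbasal must be > 0")
  stopifnot(inherits(forcing, "insulin_forcing"))
  structure(list(subject_id = as.character(subject_id), test_type = test_type,
                 dose = as.numeric(dose), obs_times = as.numeric(obs_times),
                 obs_glucose = as.numeric(obs_glucose), forcing = forcing,
                 Gbasal = as.numeric(Gbasal), Ibasal = as.numeric(Ibasal),
                 covariates = covariates),
            class = "subject_data")
}

#' Convert a weight-based glucose dose to mmol
#'
#' @param dose_g_per_kg Dose in g/kg (0.3 for the standard IVGTT bolus).
#' @param weight Body weight in kg.
#' @return Dose in mmol (molar mass of glucose 180.16 g/mol).
#' @export
dose_to_mmol <- function(dose_g_per_kg, weight) {
  if (any(!is.finite(dose_g_per_kg)) || any(dose_g_per_kg <= 0))
    abort_invalid("dose_g_per_kg must be > 0")
  if (any(!is.finite(weight)) || any(weight <= 0))
    abort_invalid("weight must be > 0")
  dose_g_per_kg * weight * 1000 / MW_GLUCOSE
}

#' Evaluate the insulin forcing at arbitrary times
#'
#' Linear interpolation between knots, constant extrapolation beyond the
#' measured range.
#'
#' @param forcing An [insulin_forcing()].
#' @param t Times in minutes (vectorized), `t >= 0`.
#' @return Insulin concentrations in pmol/L.
#' @export
interpolate_insulin <- function(forcing, t) {
  if (!inherits(forcing, "insulin_forcing")) abort_invalid("forcing must be an insulin_forcing")
  if (any(t < 0)) abort_invalid("t must be >= 0")
  stats::approx(forcing$times, forcing$concentrations, xout = t, rule = 2)$y
}

#' Simulate the glucose minimal model
#'
#' Solves the two-state system with an adaptive embedded Runge-Kutta scheme;
#' forcing knots and requested output times are mandatory step boundaries so
#' the integrator never crosses a kink in I(t).
#'
#' @param params An [mm_params()] vector (or positive named numeric).
#' @param dose Glucose dose, mmol.
#' @param Gbasal Basal glucose, mmol/L.
#' @param Ibasal Basal insulin, pmol/L.
#' @param forcing An [insulin_forcing()].
#' @param eval_times Output times (minutes), non-decreasing, `>= 0`.
#' @param ode_rtol,ode_atol Solver tolerances.
#' @param return_state If `TRUE` return a data.frame with columns `time`,
#'   `G` and `X`; otherwise the glucose vector only.
#' @return Glucose concentrations (mmol/L) at `eval_times`, or the full state.
#' @export
simulate_glucose <- function(params, dose, Gbasal, Ibasal, forcing, eval_times,
                             ode_rtol = 1e-8, ode_atol = 1e-10,
                             return_state = FALSE) {
  th <- unclass(params)[MM_PARS]
  if (any(!is.finite(th)) || any(th <= 0))
    abort_invalid("params must contain positive GEZI, SI, p2, V")
  if (any(eval_times < 0)) abort_invalid("eval_times must be >= 0")
  if (any(diff(eval_times) < 0)) abort_invalid("eval_times must be non-decreasing")
  ut <- unique(eval_times)
  m <- tryCatch(
    mm_simulate_cpp(as.numeric(th), dose, Gbasal, Ibasal,
                    forcing$times, forcing$concentrations, ut, ode_rtol, ode_atol),
    error = function(e) abort_numerical(conditionMessage(e))
  )
  idx <- match(eval_times, ut)
  if (return_state) {
    data.frame(time = eval_times, G = unname(m[idx, 1]), X = unname(m[idx, 2]))
  } else {
    unname(m[idx, 1])
  }
}

#' Closed-form glucose decay under constant insulin
#'
#' With I(t) held at `Ibasal`, X(t) stays at its basal value and the glucose
#' equation collapses to a linear constant-coefficient ODE with solution
#' `Gbasal + (Dose/V) * exp(-(GEZI + SI*Ibasal) * t)`. Used as an analytic
#' oracle for the numerical solver.
#'
#' @inheritParams simulate_glucose
#' @param t Times in minutes (vectorized), `t >= 0`.
#' @export
glucose_closed_form_constant_insulin <- function(params, dose, Gbasal, Ibasal, t) {
  th <- unclass(params)[MM_PARS]
  if (any(!is.finite(th)) || any(th <= 0))
    abort_invalid("params must contain positive GEZI, SI, p2, V")
  if (any(t < 0)) abort_invalid("t must be >= 0")
  Gbasal + (dose / th[["V"]]) * exp(-(th[["GEZI"]] + th[["SI"]] * Ibasal) * t)
}

#' Drop glucose samples before 5 minutes
#'
#' The one-compartment glucose model does not represent the initial mixing
#' phase, so observations at t < 5 min are excluded before fitting. The
#' insulin forcing is left untouched.
#'
#' @param subject A [subject_data()] object.
#' @return A copy with early glucose observations removed.
#' @export
filter_early_samples <- function(subject) {
  stopifnot(inherits(subject, "subject_data"))
  keep <- subject$obs_times >= 5
  if (sum(keep) < 4)
    abort_insufficient(sprintf(
      "subject %s has only %d glucose observations at t >= 5 min (need >= 4)",
      subject$subject_id, sum(keep)))
  subject$obs_times <- subject$obs_times[keep]
  subject$obs_glucose <- subject$obs_glucose[keep]
  subject
}

#' Apply the early-sample filter to a whole dataset
#'
#' @param subjects List of [subject_data()] objects.
#' @return Filtered list.
#' @export
filter_dataset <- function(subjects) {
  lapply(subjects, filter_early_samples)
}

#' @export
print.subject_data <- function(x, ...) {
  cat(sprintf("<subject %s> %s, dose %.1f mmol, %d glucose obs (%g..%g min), Gb %.2f mmol/L, Ib %.1f pmol/L\n",
              x$subject_id, x$test_type, x$dose, length(x$obs_times),
              min(x$obs_times), max(x$obs_times), x$Gbasal, x$Ibasal))
  invisible(x)
}
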
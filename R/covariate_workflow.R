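# Forward covariate-selection procedure: exploratory screening on the
# empirical conditional means of a covariate-free fit, ordered one-by-one
# addition (SI first, then V, then GEZI, then p2), LRT gating at p < alpha,
# and a structured final report.

#' Screen covariates against empirical conditional means
#'
#' For continuous covariates, Spearman rank correlation between the
#' conditional-mean log-parameters and the covariate; for two-level
#' categorical covariates, a Wilcoxon rank-sum comparison; for more levels,
#' a Kruskal-Wallis test. Constant covariates are skipped with a warning.
#' Screening is advisory: final inclusion is decided by full refits.
#'
#' @param fit_base Covariate-free [em_fit()] result.
#' @param covariate_table Data frame with `subject_id` plus covariate
#'   columns.
#' @return Data frame (parameter, covariate, kind_suggested, statistic,
#'   p_value) ordered by p-value within parameter.
#' @export
ebe_screen <- function(fit_base, covariate_table) {
  stopifnot(inherits(fit_base, "mm_fit"))
  ids <- rownames(fit_base$conditional_mean_log)
  tb <- covariate_table[match(ids, covariate_table$subject_id), , drop = FALSE]
  cand_cols <- setdiff(names(tb), c("subject_id", "dose_mmol"))
  rows <- list()
  for (par in MM_PARS) {
    y <- fit_base$conditional_mean_log[, par]
    for (cv in cand_cols) {
      x <- tb[[cv]]
      ux <- unique(x[!is.na(x)])
      if (length(ux) < 2) {
        warning(sprintf("covariate '%s' is constant; skipped", cv))
        next
      }
      if (is.numeric(x) && length(ux) > 2) {
        ct <- suppressWarnings(cor.test(y, x, method = "spearman", exact = FALSE))
        rows[[length(rows) + 1]] <- data.frame(
          parameter = par, covariate = cv, kind_suggested = "power_centered",
          statistic = unname(ct$estimate), p_value = ct$p.value)
      } else if (length(ux) == 2) {
        g <- x == ux[[1]]
        wt <- suppressWarnings(wilcox.test(y[g], y[!g], exact = FALSE))
        delta <- mean(y[g]) - mean(y[!g])
        rows[[length(rows) + 1]] <- data.frame(
          parameter = par, covariate = cv, kind_suggested = "proportional_shift",
          statistic = delta, p_value = wt$p.value)
      } else {
        kt <- kruskal.test(y, factor(x))
        rows[[length(rows) + 1]] <- data.frame(
          parameter = par, covariate = cv, kind_suggested = "proportional_shift",
          statistic = unname(kt$statistic), p_value = kt$p.value)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(match(out$parameter, MM_PARS), out$p_value), , drop = FALSE]
}

# Profile likelihood-ratio gate for one candidate effect.
#
# Importance samples of every subject's conditional posterior are built once
# under the current (reduced) model and cached; the candidate coefficient
# gamma enters the marginal likelihood only through the stage-2 prior
# density, so the profile -2 log likelihood over gamma is an analytic
# reweighting of the cached samples. Any misconvergence of the reduced-model
# estimates is common to every gamma and cancels exactly in the
# likelihood-ratio difference, which keeps the test calibrated without
# requiring two fully converged refits. The candidate's design column is
# centered so the gamma direction is orthogonal to the population mean and
# the fixed-nuisance profile matches the full-model likelihood ratio to
# first order.
profile_gate <- function(dataset, pop_red, cand, settings,
                         n_samples = 4L * settings$n_importance_samples,
                         gamma_lim = c(-4, 4)) {
  n <- length(dataset)
  k <- match(cand$parameter, MM_PARS)
  x <- vapply(dataset, function(s) {
    v <- s$covariates[[cand$covariate]]
    if (is.null(v) || length(v) != 1 || is.na(v))
      abort_config(sprintf("covariate '%s' required by the candidate is missing",
                           cand$covariate))
    v <- as.numeric(v)
    if (cand$kind == "power_centered") log(v / cand$reference) else v
  }, 0)
  if (sd(x) < 1e-12)
    return(list(delta = 0, p_value = 1, gamma = 0,
                note = "constant covariate"))
  x <- x - mean(x)
  cache <- vector("list", n)
  m0 <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    s <- dataset[[i]]
    m_i <- individual_mean_log(pop_red, s$covariates)
    r <- estep_subject(s, m_i, pop_red$Sigma_log, pop_red$sigma_prop, settings,
                       mode0 = m_i,
                       seed = derive_seed(settings$seed, s$subject_id, "gate"),
                       n_samples = n_samples, optim_maxit = 25,
                       keep_samples = TRUE)
    if (is.null(r))
      abort_numerical(sprintf("gate evaluation failed for subject %s",
                              s$subject_id))
    cache[[i]] <- r
    m0[i, ] <- m_i
  }
  m2_of <- function(gamma) {
    tot <- 0
    for (i in seq_len(n)) {
      r <- cache[[i]]
      mi <- m0[i, ]
      mi[k] <- mi[k] + gamma * x[i]
      lw <- r$log_lik + dmvnorm_log_rows(r$samples, mi, pop_red$Sigma_log) -
        r$log_prop
      ok <- is.finite(lw)
      a <- max(lw[ok])
      tot <- tot + (a + log(sum(exp(lw[ok] - a)) / length(lw)))
    }
    -2 * tot
  }
  opt <- stats::optimize(m2_of, interval = gamma_lim)
  d <- max(m2_of(0) - opt$objective, 0)
  list(delta = d, p_value = pchisq(d, 1, lower.tail = FALSE),
       gamma = opt$minimum)
}

#' Forward one-by-one covariate selection
#'
#' Candidates are ordered by parameter priority (SI, then V, then GEZI,
#' then p2, reflecting how much prior evidence supports each parameter's
#' covariate dependence) and added one at a time. Each step computes a
#' profile likelihood-ratio statistic for the candidate coefficient by
#' reweighting cached conditional-posterior samples of the current model
#' (see the package vignette): the current model's estimation error is
#' common to every coefficient value and cancels exactly in the ratio,
#' which keeps the gate calibrated without two fully converged refits per
#' candidate. Candidates passing the gate (`p < alpha`) are refit in full
#' to estimate their coefficients, and retention additionally requires the
#' coefficient's RSE below `rse_threshold` when that threshold is finite.
#'
#' @param dataset List of pre-filtered [subject_data()] objects.
#' @param candidates List of [covariate_effect()] stubs to test.
#' @param settings A [fit_settings()] object.
#' @param alpha LRT significance level (0.05).
#' @param rse_threshold Retention also requires the new coefficient's RSE-CV%
#'   below this value; set `Inf` to gate on the LRT alone.
#' @param base_fit Optional pre-computed covariate-free fit.
#' @param priority Parameter testing order.
#' @return List with `spec` (retained effects), `steps` (step table),
#'   `fit` (final fit) and `base_fit`.
#' @export
forward_select <- function(dataset, candidates, settings = fit_settings(),
                           alpha = 0.05, rse_threshold = 50,
                           base_fit = NULL,
                           priority = c("SI", "V", "GEZI", "p2")) {
  if (is.null(base_fit))
    base_fit <- em_fit(dataset, spec = NULL, settings = settings)
  if (length(candidates) == 0) {
    return(list(spec = list(), steps = data.frame(), fit = base_fit,
                base_fit = base_fit))
  }
  ord <- order(match(vapply(candidates, `[[`, "", "parameter"), priority))
  candidates <- candidates[ord]

  cur_fit <- base_fit
  cur_spec <- list()
  steps <- list()
  for (cand in candidates) {
    lab <- effect_label(cand)
    gate <- tryCatch(
      profile_gate(dataset, cur_fit$pop, cand, settings),
      error = function(e) e)
    if (inherits(gate, "error")) {
      steps[[length(steps) + 1]] <- data.frame(
        step = length(steps) + 1, effect = lab, minus2LL = NA_real_,
        delta = NA_real_, df = 1, p_value = NA_real_, rse = NA_real_,
        decision = paste0("rejected (gate failed: ",
                          conditionMessage(gate), ")"))
      next
    }
    keep <- gate$p_value < alpha
    rse_j <- NA_real_
    m2_new <- NA_real_
    fit_try <- NULL
    if (keep) {
      # the candidate passed the likelihood gate: refit the extended model
      # to estimate its coefficient (and precision, when gated on RSE)
      start <- cand
      start$coefficient <- if (cand$kind == "proportional_shift")
        expm1(gate$gamma) else gate$gamma
      trial_spec <- c(cur_spec, list(start))
      init <- cur_fit$pop
      init$effects <- trial_spec
      fit_try <- tryCatch(
        suppressWarnings(em_fit(dataset, spec = trial_spec, init = init,
                                settings = settings)),
        error = function(e) NULL)
      if (is.null(fit_try)) {
        keep <- FALSE
        rse_j <- Inf
      } else {
        m2_new <- as.numeric(fit_try$minus2LL)
        if (is.finite(rse_threshold)) {
          ses <- tryCatch(standard_errors(fit_try, dataset, settings),
                          error = function(e) NULL)
          rse_j <- if (is.null(ses)) Inf else unname(ses$rse[lab])
          keep <- is.finite(rse_j) && rse_j < rse_threshold
        }
      }
    }
    steps[[length(steps) + 1]] <- data.frame(
      step = length(steps) + 1, effect = lab,
      minus2LL = m2_new, delta = gate$delta,
      df = 1, p_value = gate$p_value, rse = rse_j,
      decision = if (keep) "retained" else "rejected")
    if (keep) {
      cur_spec <- fit_try$spec  # fitted effects, coefficients updated
      cur_fit <- fit_try
    }
  }
  list(spec = cur_spec, steps = do.call(rbind, steps), fit = cur_fit,
       base_fit = base_fit)
}

#' Structured base-vs-final model report
#'
#' Mirrors the usual population-modeling results table: typical values, IIV
#' CV%, covariate coefficients, proportional error and -2 log likelihood for
#' both models, plus the overall likelihood-ratio test.
#'
#' @param fit_final,fit_base [em_fit()] results for the covariate and
#'   covariate-free models.
#' @param rse_final,rse_base Optional [standard_errors()] results to embed.
#' @return List of class `mm_report` (JSON-serializable).
#' @export
final_model_report <- function(fit_final, fit_base,
                               rse_final = NULL, rse_base = NULL) {
  one <- function(fit, rse) {
    list(typical_values = as.list(typical_values(fit$pop)),
         iiv_cv_percent = as.list(iiv_cv(fit$pop$Sigma_log)),
         covariate_effects = lapply(fit$spec, function(e)
           list(parameter = e$parameter, covariate = e$covariate,
                kind = e$kind, reference = e$reference,
                coefficient = e$coefficient)),
         sigma_prop = fit$pop$sigma_prop,
         minus2LL = as.numeric(fit$minus2LL),
         rse_cv_percent = if (!is.null(rse)) as.list(rse$rse) else NULL)
  }
  df_extra <- length(fit_final$spec) - length(fit_base$spec)
  overall <- if (df_extra >= 1) {
    lrt(as.numeric(fit_base$minus2LL), as.numeric(fit_final$minus2LL),
        df = df_extra, tolerance = 6 * attr(fit_base$minus2LL, "mc_se"))
  } else NULL
  structure(list(base = one(fit_base, rse_base),
                 final = one(fit_final, rse_final),
                 lrt = overall),
            class = "mm_report")
}
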
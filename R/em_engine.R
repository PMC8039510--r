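# Maximum-likelihood nonlinear mixed-effects estimation by Monte-Carlo EM.
#
# E-step: per subject, a Laplace approximation of the conditional posterior
# of logtheta_i (mode + curvature) anchors a defensive mixture proposal
# (mode-centered multivariate-t plus the prior itself, balance-heuristic
# weights); conditional first/second moments, the marginal likelihood and
# the expected residual sum of squares are computed from the normalized
# weights. All draws are seeded per (seed, subject, iteration), so fits are
# bit-reproducible and invariant to subject order.
#
# M-step (closed form): fixed effects and covariate coefficients by
# generalized least squares on the conditional means; Sigma from pooled
# conditional second moments; sigma from the expected relative residual sum
# of squares.

#' Estimation settings
#'
#' @param n_importance_samples Importance samples per subject per iteration.
#' @param max_iterations EM iteration cap.
#' @param convergence_rtol Relative-change threshold; the fit is declared
#'   converged once all estimates move less than this for 5 consecutive
#'   iterations (on traces smoothed over 3 iterations).
#' @param seed Integer seed controlling every random draw of the fit.
#' @param ode_rtol,ode_atol Solver tolerances used inside the EM loops.
#' @return Object of class `fit_settings`.
#' @export
fit_settings <- function(n_importance_samples = 100, max_iterations = 40,
                         convergence_rtol = 2e-3, seed = 1,
                         ode_rtol = 1e-6, ode_atol = 1e-8) {
  if (n_importance_samples < 10) abort_invalid("need at least 10 importance samples")
  if (max_iterations < 1) abort_invalid("max_iterations must be >= 1")
  if (convergence_rtol <= 0 || convergence_rtol >= 1)
    abort_invalid("convergence_rtol must be in (0, 1)")
  structure(list(n_importance_samples = as.integer(n_importance_samples),
                 max_iterations = as.integer(max_iterations),
                 convergence_rtol = convergence_rtol, seed = as.integer(seed),
                 ode_rtol = ode_rtol, ode_atol = ode_atol),
            class = "fit_settings")
}

#' Observation log-likelihood for one subject at fixed parameters
#'
#' Gaussian log-density of the glucose residuals under the proportional-SD
#' error model: `y_j ~ N(f_j, (sigma_prop * f_j)^2)` with `f` the model
#' prediction at `exp(logtheta)`. The subject is expected to be pre-filtered
#' (no observations before 5 min).
#'
#' @param subject A [subject_data()] object.
#' @param logtheta Numeric 4-vector, log(GEZI, SI, p2, V).
#' @param sigma_prop Proportional-error scale.
#' @param ode_rtol,ode_atol Solver tolerances.
#' @return Scalar log-likelihood (`-Inf` if the solver fails).
#' @export
individual_loglik <- function(subject, logtheta, sigma_prop,
                              ode_rtol = 1e-8, ode_atol = 1e-10) {
  stopifnot(inherits(subject, "subject_data"))
  m <- mm_loglik_cpp(matrix(as.numeric(logtheta), 1, 4), subject$dose,
                     subject$Gbasal, subject$Ibasal,
                     subject$forcing$times, subject$forcing$concentrations,
                     subject$obs_times, subject$obs_glucose,
                     sigma_prop, ode_rtol, ode_atol)
  as.numeric(m[1, 1])
}

# ---- internal machinery ----------------------------------------------------

# 4 x p design matrix of log-scale covariate regressors for one subject
effects_design <- function(effects, covariates) {
  p <- length(effects)
  D <- matrix(0, 4, p, dimnames = list(MM_PARS, vapply(effects, effect_label, "")))
  for (j in seq_len(p)) {
    e <- effects[[j]]
    v <- covariates[[e$covariate]]
    if (is.null(v) || length(v) != 1 || is.na(v))
      abort_config(sprintf("covariate '%s' required by the model is missing", e$covariate))
    v <- as.numeric(v)
    D[e$parameter, j] <- if (e$kind == "power_centered") log(v / e$reference) else v
  }
  D
}

# natural-scale coefficient -> log-scale gamma and back
gamma_of_effect <- function(e) {
  if (e$kind == "proportional_shift") log1p(e$coefficient) else e$coefficient
}
effect_with_gamma <- function(e, g) {
  e$coefficient <- if (e$kind == "proportional_shift") expm1(g) else g
  e
}

# physically plausible search box on the log scale; the conditional
# posterior is restricted to it so line searches and proposal tails cannot
# drive the solver into absurdly stiff corners
LOG_BOX_LO <- log(c(1e-5, 1e-9, 1e-4, 1))
LOG_BOX_HI <- log(c(0.5, 1e-2, 2, 100))

# batched negative log-posterior pieces for one subject
subject_batch_loglik <- function(s, U, sigma, ode_rtol, ode_atol) {
  mm_loglik_cpp(U, s$dose, s$Gbasal, s$Ibasal,
                s$forcing$times, s$forcing$concentrations,
                s$obs_times, s$obs_glucose, sigma, ode_rtol, ode_atol)
}

# Laplace mode + multivariate-t importance sampling for one subject.
# Returns conditional moments, marginal likelihood and E[SSR_rel].
estep_subject <- function(s, m_i, Sigma, sigma, settings, mode0, seed,
                          n_samples = settings$n_importance_samples,
                          optim_maxit = 30, keep_samples = FALSE,
                          H_prev = NULL, mode_prev = NULL) {
  rtol <- settings$ode_rtol; atol <- settings$ode_atol
  Lsig <- chol(Sigma)
  ldet_prior <- sum(log(diag(Lsig))) + 2 * log(2 * pi)
  negpost <- function(u) {
    ll <- subject_batch_loglik(s, matrix(u, 1, 4), sigma, rtol, atol)[1, 1]
    z <- backsolve(Lsig, u - m_i, transpose = TRUE)
    v <- -(ll - 0.5 * sum(z^2) - ldet_prior)
    if (!is.finite(v)) 1e10 else v
  }
  mode0 <- pmin(pmax(mode0, LOG_BOX_LO + 1e-6), LOG_BOX_HI - 1e-6)
  opt <- tryCatch(
    optim(mode0, negpost, method = "L-BFGS-B",
          lower = LOG_BOX_LO, upper = LOG_BOX_HI,
          control = list(maxit = optim_maxit, factr = 1e6)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) {
    opt <- tryCatch(
      optim(pmin(pmax(m_i, LOG_BOX_LO + 1e-6), LOG_BOX_HI - 1e-6),
            negpost, method = "Nelder-Mead", control = list(maxit = 300)),
      error = function(e) NULL)
  }
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9)
    return(NULL)
  mode <- opt$par
  f0 <- opt$value

  # reuse the cached curvature when a warm-started mode has barely moved
  if (!is.null(H_prev) && !is.null(mode_prev) &&
      max(abs(mode - mode_prev)) < 0.05) {
    H <- H_prev
    S <- make_spd(solve(H), floor = 1e-12)
    return(estep_sample(s, m_i, Sigma, sigma, mode, H, S, seed, n_samples,
                        rtol, atol, length(s$obs_times), keep_samples))
  }

  # central-difference Hessian, batched through the C++ likelihood
  h <- 1e-3
  P <- matrix(mode, 33, 4, byrow = TRUE)
  row <- 1
  diag_idx <- matrix(0L, 4, 2)
  for (j in 1:4) {
    P[row, j] <- mode[j] + h; P[row + 1, j] <- mode[j] - h
    diag_idx[j, ] <- c(row, row + 1L); row <- row + 2L
  }
  pairs <- which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE)
  pair_idx <- matrix(0L, nrow(pairs), 4)
  for (q in seq_len(nrow(pairs))) {
    j <- pairs[q, 1]; k <- pairs[q, 2]
    P[row, c(j, k)] <- mode[c(j, k)] + h
    P[row + 1, c(j, k)] <- mode[c(j, k)] - h
    P[row + 2, j] <- mode[j] + h; P[row + 2, k] <- mode[k] - h
    P[row + 3, j] <- mode[j] - h; P[row + 3, k] <- mode[k] + h
    pair_idx[q, ] <- row:(row + 3L); row <- row + 4L
  }
  llp <- subject_batch_loglik(s, P, sigma, rtol, atol)[, 1]
  fp <- -(llp + dmvnorm_log_rows(P, m_i, Sigma))
  H <- matrix(0, 4, 4)
  if (all(is.finite(fp))) {
    for (j in 1:4)
      H[j, j] <- (fp[diag_idx[j, 1]] + fp[diag_idx[j, 2]] - 2 * f0) / h^2
    for (q in seq_len(nrow(pairs))) {
      j <- pairs[q, 1]; k <- pairs[q, 2]
      H[j, k] <- H[k, j] <- (fp[pair_idx[q, 1]] + fp[pair_idx[q, 2]] -
                             fp[pair_idx[q, 3]] - fp[pair_idx[q, 4]]) / (4 * h^2)
    }
  }
  Hok <- all(is.finite(H)) && all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0)
  if (!Hok) H <- solve(Sigma)  # prior curvature as a safe lower bound
  S <- make_spd(solve(H), floor = 1e-12)
  estep_sample(s, m_i, Sigma, sigma, mode, H, S, seed, n_samples,
               rtol, atol, length(s$obs_times), keep_samples)
}

# Defensive multiple importance sampling for the conditional posterior.
# The proposal is an equal mixture of a multivariate-t (df = 4) centered at
# the mode with the Laplace curvature and the prior itself: the prior
# component exactly covers the weakly identified directions in which the
# posterior collapses onto the prior and is strongly left-skewed on the
# log scale (notably SI), where a symmetric mode-centered proposal alone
# under-covers the long tail and biases the conditional mean. If the
# weights still degenerate, a third component recentered at the estimated
# moments is added. All components are combined with the balance heuristic,
# which keeps both the moments and the marginal-likelihood estimate
# consistent. Near-unbiased E-step moments matter disproportionately here
# because flat likelihood ridges amplify any E-step bias in the EM fixed
# point.
estep_sample <- function(s, m_i, Sigma, sigma, mode, H, S, seed, n_samples,
                         rtol, atol, n_obs, keep_samples) {
  df <- 4
  set.seed(seed)
  draw_t <- function(center, L, M) {
    Z <- matrix(rnorm(4 * M), M, 4)
    g <- rchisq(M, df) / df
    sweep((Z %*% L) / sqrt(g), 2, center, "+")
  }
  draw_norm <- function(center, L, M) {
    sweep(matrix(rnorm(4 * M), M, 4) %*% L, 2, center, "+")
  }
  dmvt_log <- function(U, center, L) {
    Zt <- backsolve(L, t(U) - center, transpose = TRUE)
    qf <- colSums(Zt^2)
    lgamma((df + 4) / 2) - lgamma(df / 2) - 2 * log(df * pi) -
      sum(log(diag(L))) - ((df + 4) / 2) * log1p(qf / df)
  }
  eval_target <- function(U) {
    n <- nrow(U)
    inbox <- rowSums(sweep(U, 2, LOG_BOX_LO, ">=") &
                     sweep(U, 2, LOG_BOX_HI, "<=")) == 4
    ll <- rep(-Inf, n)
    lik <- matrix(NA_real_, n, 3)
    if (any(inbox)) {
      lik[inbox, ] <- subject_batch_loglik(s, U[inbox, , drop = FALSE],
                                           sigma, rtol, atol)
      ll[inbox] <- lik[inbox, 1]
    }
    list(ll = ll, lik = lik)
  }
  moments <- function(U, lw, lik) {
    ok <- is.finite(lw)
    if (!any(ok)) return(NULL)
    a <- max(lw[ok])
    w <- ifelse(ok, exp(lw - a), 0)
    sw <- sum(w)
    wn <- w / sw
    b <- colSums(wn * U)
    Rm <- sweep(U, 2, b)
    Vc <- crossprod(Rm * sqrt(wn))
    mw <- sw / length(w)
    list(b = b, V = (Vc + t(Vc)) / 2, wn = wn,
         lmarg = a + log(mw), ess = 1 / sum(wn^2),
         essr = sum(wn[ok] * lik[ok, 2]),
         mc_var = (sum((w - mw)^2) / (length(w) - 1)) / (length(w) * mw^2))
  }
  dmvnorm_chol_log <- function(U, center, L) {
    Zt <- backsolve(L, t(U) - center, transpose = TRUE)
    -0.5 * colSums(Zt^2) - sum(log(diag(L))) - 2 * log(2 * pi)
  }
  # draw one component (samples are drawn and the target evaluated once per
  # component; adding a component later reuses earlier evaluations)
  new_comp <- function(type, center, L, M) {
    U <- if (type == "t") draw_t(center, L, M) else draw_norm(center, L, M)
    list(type = type, center = center, L = L, M = M, U = U,
         ev = eval_target(U), lp = dmvnorm_log_rows(U, m_i, Sigma))
  }
  # balance-heuristic weights over the current component stack
  mix_moments <- function(comps) {
    U <- do.call(rbind, lapply(comps, `[[`, "U"))
    N <- nrow(U)
    ll <- unlist(lapply(comps, function(cp) cp$ev$ll))
    lik <- do.call(rbind, lapply(comps, function(cp) cp$ev$lik))
    lp <- unlist(lapply(comps, `[[`, "lp"))
    lqs <- vapply(comps, function(cp) {
      if (cp$type == "t") dmvt_log(U, cp$center, cp$L)
      else dmvnorm_chol_log(U, cp$center, cp$L)
    }, numeric(N))
    wts <- vapply(comps, `[[`, 0, "M") / N
    a <- apply(lqs, 1, max)
    lq_mix <- a + log(as.vector(exp(lqs - a) %*% wts))
    res <- moments(U, ll + lp - lq_mix, lik)
    if (!is.null(res)) {
      res$U <- U
      res$ll <- ll
      res$lq <- lq_mix
    }
    res
  }

  M <- n_samples
  M1 <- ceiling(M / 2)
  comps <- list(new_comp("t", mode, chol(S), M1),
                new_comp("norm", m_i, chol(Sigma), M - M1))
  r1 <- mix_moments(comps)
  if (is.null(r1)) return(NULL)

  if (r1$ess < 0.5 * M) {
    S2 <- make_spd(1.5 * r1$V, floor = max(diag(r1$V)) * 1e-6 + 1e-12)
    set.seed(derive_seed(seed, "round2"))
    comps <- c(comps, list(new_comp("t", r1$b, chol(S2), M)))
    r2 <- mix_moments(comps)
    if (!is.null(r2)) r1 <- r2
  }
  U <- r1$U
  b <- r1$b; Vc <- r1$V; wn <- r1$wn
  names(mode) <- names(b) <- MM_PARS
  dimnames(Vc) <- list(MM_PARS, MM_PARS)
  out <- list(mode = mode, mean = b, cov = Vc, marginal_loglik = r1$lmarg,
              ess = r1$ess, essr = r1$essr, mc_var = r1$mc_var,
              n_obs = n_obs, H = H)
  if (keep_samples) {
    out$samples <- U
    out$weights <- wn
    out$log_lik <- r1$ll
    out$log_prop <- r1$lq
  }
  out
}

check_filtered <- function(dataset) {
  bad <- vapply(dataset, function(s) any(s$obs_times < 5), logical(1))
  if (any(bad))
    abort_invalid(paste0(
      "subjects with glucose observations before 5 min: ",
      paste(vapply(dataset[bad], `[[`, "", "subject_id"), collapse = ", "),
      "; apply filter_early_samples()/filter_dataset() first"))
  invisible(TRUE)
}

#' Conditional (empirical Bayes) posterior of one subject's parameters
#'
#' Maximizes the individual log-likelihood plus log-prior to find the
#' conditional mode, then draws importance samples from a multivariate-t
#' proposal with the Laplace curvature at the mode.
#'
#' @param subject A [subject_data()] object (pre-filtered).
#' @param pop A [population_params()] object.
#' @param settings A [fit_settings()] object.
#' @return List with `mode`, `mean`, `cov` (log scale), `samples`, `weights`,
#'   `ess` and `marginal_loglik`.
#' @export
conditional_posterior <- function(subject, pop, settings = fit_settings()) {
  m_i <- individual_mean_log(pop, subject$covariates)
  res <- estep_subject(subject, m_i, pop$Sigma_log, pop$sigma_prop, settings,
                       mode0 = m_i,
                       seed = derive_seed(settings$seed, subject$subject_id, "cp"),
                       keep_samples = TRUE)
  if (is.null(res))
    abort_numerical(sprintf("conditional mode search failed for subject %s",
                            subject$subject_id))
  res
}

#' Crude per-subject fits used to initialize the population model
#'
#' Each subject gets a quick MAP estimate under a weak log-normal prior
#' centered at heuristic starting values (V from the extrapolated glucose
#' peak, literature-scale GEZI/SI/p2); the log-estimates are pooled into
#' starting values for the population mean, covariance and error scale.
#'
#' @param dataset List of pre-filtered [subject_data()] objects.
#' @param settings A [fit_settings()] object.
#' @param effects Covariate effects of the model to be fitted (their
#'   coefficients initialize at their current values).
#' @return A [population_params()] object.
#' @export
init_population <- function(dataset, settings = fit_settings(), effects = list()) {
  prior_sd <- c(0.8, 1.2, 0.8, 0.4)
  est <- matrix(NA_real_, length(dataset), 4)
  ssr_tot <- 0; n_tot <- 0
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    V0 <- s$dose / max(max(s$obs_glucose) - s$Gbasal, 0.5)
    V0 <- min(max(V0, 3), 40)
    th0 <- log(c(0.02, 4e-5, 0.04, V0))
    P0 <- diag(1 / prior_sd^2)
    negpost <- function(u) {
      ll <- subject_batch_loglik(s, matrix(u, 1, 4), 0.08,
                                 settings$ode_rtol, settings$ode_atol)[1, 1]
      v <- -ll + 0.5 * sum(((u - th0) / prior_sd)^2)
      if (!is.finite(v)) 1e10 else v
    }
    opt <- tryCatch(optim(th0, negpost, method = "L-BFGS-B",
                          lower = LOG_BOX_LO, upper = LOG_BOX_HI,
                          control = list(maxit = 40, factr = 1e6)),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) {
      est[i, ] <- th0
    } else {
      est[i, ] <- opt$par
      lk <- subject_batch_loglik(s, matrix(opt$par, 1, 4), 0.08,
                                 settings$ode_rtol, settings$ode_atol)
      if (is.finite(lk[1, 2])) {
        ssr_tot <- ssr_tot + lk[1, 2]
        n_tot <- n_tot + length(s$obs_times)
      }
    }
  }
  mu <- colMeans(est)
  S <- stats::cov(est)
  S <- 0.7 * S + 0.3 * diag(diag(S))
  S <- make_spd(S, floor = 1e-4)
  sigma0 <- if (n_tot > 0) max(sqrt(ssr_tot / n_tot), 0.02) else 0.08
  population_params(setNames(mu, MM_PARS), S, effects = effects,
                    sigma_prop = sigma0)
}

#' Fit the hierarchical minimal model by Monte-Carlo EM
#'
#' @param dataset List of pre-filtered [subject_data()] objects (>= 2; at
#'   least 10 recommended for a stable covariance estimate).
#' @param spec Optional list of [covariate_effect()] objects defining the
#'   covariate model (their coefficients are starting values).
#' @param init Optional [population_params()] starting point; defaults to
#'   [init_population()].
#' @param settings A [fit_settings()] object.
#' @return Object of class `mm_fit` with elements `pop`, `minus2LL`,
#'   `conditional_mean_log`, `conditional_cov_log`, `trace`, `converged`,
#'   `ess`, `settings`, `spec`.
#' @export
em_fit <- function(dataset, spec = NULL, init = NULL, settings = fit_settings()) {
  if (length(dataset) < 2) abort_invalid("need at least 2 subjects")
  if (length(dataset) < 10)
    warning("fewer than 10 subjects; population covariance will be poorly determined")
  check_filtered(dataset)
  effects <- if (is.null(spec)) list() else spec
  p <- length(effects)
  n <- length(dataset)
  ids <- vapply(dataset, `[[`, "", "subject_id")

  if (is.null(init)) init <- init_population(dataset, settings, effects)
  beta <- c(init$mu_log, vapply(effects, gamma_of_effect, 0))
  Sigma <- init$Sigma_log
  sigma <- init$sigma_prop

  A <- lapply(dataset, function(s) cbind(diag(4), effects_design(effects, s$covariates)))
  modes <- lapply(seq_len(n), function(i) drop(A[[i]] %*% beta))
  Hs <- vector("list", n)  # cached curvature per subject (proposal only;
                           # weights always use exact densities)

  est_vec <- function(beta, Sigma, sigma)
    c(beta, Sigma[lower.tri(Sigma, diag = TRUE)], sigma)
  trace_m2ll <- numeric(0)
  trace_est <- list()
  smooth3 <- function(hist) {
    k <- length(hist)
    Reduce(`+`, hist[max(1, k - 2):k]) / length(max(1, k - 2):k)
  }
  consec <- 0L
  converged <- FALSE
  prev_smoothed <- NULL
  iter_done <- 0L

  run_estep <- function(iter, n_samples = settings$n_importance_samples) {
    B <- matrix(NA_real_, n, 4)
    Vs <- vector("list", n)
    lmargs <- numeric(n); essrs <- numeric(n); esss <- numeric(n)
    mcv <- numeric(n); nobs <- integer(n)
    maxit <- if (iter == 1) 30 else if (iter <= 3) 10 else 3
    for (i in seq_len(n)) {
      s <- dataset[[i]]
      m_i <- drop(A[[i]] %*% beta)
      r <- estep_subject(s, m_i, Sigma, sigma, settings, mode0 = modes[[i]],
                         seed = derive_seed(settings$seed, s$subject_id, iter),
                         n_samples = n_samples, optim_maxit = maxit,
                         H_prev = if (iter > 3) Hs[[i]], mode_prev = modes[[i]])
      if (is.null(r)) {
        r <- estep_subject(s, m_i, Sigma, sigma, settings, mode0 = m_i,
                           seed = derive_seed(settings$seed, s$subject_id, iter),
                           n_samples = n_samples, optim_maxit = 60)
      }
      if (is.null(r))
        abort_numerical(sprintf("E-step failed for subject %s at iteration %d",
                                s$subject_id, iter))
      modes[[i]] <<- r$mode
      Hs[[i]] <<- r$H
      B[i, ] <- r$mean
      Vs[[i]] <- r$cov
      lmargs[i] <- r$marginal_loglik
      essrs[i] <- r$essr
      esss[i] <- r$ess
      mcv[i] <- r$mc_var
      nobs[i] <- r$n_obs
    }
    list(B = B, Vs = Vs, lmargs = lmargs, essrs = essrs, ess = esss,
         mc_var = mcv, nobs = nobs)
  }

  for (iter in seq_len(settings$max_iterations)) {
    e <- run_estep(iter)
    trace_m2ll <- c(trace_m2ll, -2 * sum(e$lmargs))

    # M-step
    W <- solve(Sigma)
    XtWX <- matrix(0, 4 + p, 4 + p)
    XtWb <- numeric(4 + p)
    for (i in seq_len(n)) {
      AW <- t(A[[i]]) %*% W
      XtWX <- XtWX + AW %*% A[[i]]
      XtWb <- XtWb + AW %*% e$B[i, ]
    }
    beta <- tryCatch(drop(solve(XtWX, XtWb)), error = function(e)
      abort_config(paste0("singular covariate design in the M-step; ",
                          "check that every effect's covariate varies ",
                          "across subjects (", conditionMessage(e), ")")))
    Ssum <- matrix(0, 4, 4)
    for (i in seq_len(n)) {
      r_i <- e$B[i, ] - drop(A[[i]] %*% beta)
      Ssum <- Ssum + e$Vs[[i]] + tcrossprod(r_i)
    }
    Sigma <- make_spd(Ssum / n, floor = 1e-8)
    sigma <- max(sqrt(sum(e$essrs) / sum(e$nobs)), 1e-6)

    trace_est[[iter]] <- est_vec(beta, Sigma, sigma)
    sm <- smooth3(trace_est)
    if (!is.null(prev_smoothed)) {
      rel <- max(abs(sm - prev_smoothed) / (abs(prev_smoothed) + 1e-6))
      consec <- if (rel < settings$convergence_rtol) consec + 1L else 0L
      if (consec >= 5L) { converged <- TRUE; iter_done <- iter; break }
    }
    prev_smoothed <- sm
    iter_done <- iter
  }
  if (!converged)
    warning(sprintf("EM did not meet the convergence criterion in %d iterations",
                    settings$max_iterations))

  # final E-step at the converged estimates for reporting
  ef <- run_estep(iter_done + 1L)
  m2ll <- -2 * sum(ef$lmargs)
  attr(m2ll, "mc_se") <- 2 * sqrt(sum(ef$mc_var))

  fitted_effects <- effects
  if (p > 0) {
    for (j in seq_len(p))
      fitted_effects[[j]] <- effect_with_gamma(effects[[j]], beta[4 + j])
  }
  pop <- population_params(beta[1:4], Sigma, fitted_effects, sigma)
  dimnames(ef$B) <- list(ids, MM_PARS)
  est_names <- c(paste0("mu_", MM_PARS),
                 if (p > 0) vapply(effects, effect_label, ""))
  tr <- data.frame(iteration = seq_along(trace_m2ll), minus2LL = trace_m2ll)
  est_mat <- do.call(rbind, trace_est)
  colnames(est_mat) <- c(est_names,
                         paste0("Sigma_", which(lower.tri(Sigma, diag = TRUE))),
                         "sigma_prop")
  structure(list(pop = pop, beta = setNames(beta, est_names), minus2LL = m2ll,
                 conditional_mean_log = ef$B, conditional_cov_log = ef$Vs,
                 ess = setNames(ef$ess, ids), trace = cbind(tr, est_mat),
                 converged = converged, n_iterations = iter_done,
                 settings = settings, spec = fitted_effects,
                 subject_ids = ids, n_obs = sum(ef$nobs)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> %d subjects, %d obs, %d EM iterations (%s)\n",
              length(x$subject_ids), x$n_obs, x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  -2 log likelihood: %.1f (MC se %.2f)\n",
              as.numeric(x$minus2LL), attr(x$minus2LL, "mc_se")))
  print(x$pop)
  invisible(x)
}

#' Importance-sampled marginal -2 log likelihood
#'
#' Per-subject marginal likelihoods are estimated by importance sampling
#' from the Laplace-mode multivariate-t proposal; the per-subject seeds are
#' model-independent, so likelihoods of nested models evaluated on the same
#' dataset share common random numbers and their difference has small Monte
#' Carlo error.
#'
#' @param dataset List of pre-filtered [subject_data()] objects.
#' @param pop A [population_params()] object.
#' @param settings A [fit_settings()] object.
#' @param n_samples Importance samples per subject (defaults to three times
#'   the E-step setting).
#' @return Scalar -2 log likelihood with attributes `mc_se` (Monte-Carlo
#'   standard error) and `per_subject`.
#' @export
total_minus2LL <- function(dataset, pop, settings = fit_settings(),
                           n_samples = NULL) {
  check_filtered(dataset)
  if (is.null(n_samples)) n_samples <- 2L * settings$n_importance_samples
  lm <- numeric(length(dataset)); mv <- numeric(length(dataset))
  low_ess <- character(0)
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    m_i <- individual_mean_log(pop, s$covariates)
    r <- estep_subject(s, m_i, pop$Sigma_log, pop$sigma_prop, settings,
                       mode0 = m_i,
                       seed = derive_seed(settings$seed, s$subject_id, "marglik"),
                       n_samples = n_samples, optim_maxit = 20)
    if (is.null(r))
      abort_numerical(sprintf("marginal-likelihood evaluation failed for subject %s",
                              s$subject_id))
    lm[i] <- r$marginal_loglik
    mv[i] <- r$mc_var
    if (r$ess < 0.02 * n_samples) low_ess <- c(low_ess, s$subject_id)
  }
  if (length(low_ess))
    warning(paste0("degenerate importance weights (low ESS) for subject(s): ",
                   paste(low_ess, collapse = ", ")))
  out <- -2 * sum(lm)
  attr(out, "mc_se") <- 2 * sqrt(sum(mv))
  attr(out, "per_subject") <- -2 * lm
  out
}

#' Likelihood-ratio test for nested population models
#'
#' @param minus2LL_reduced,minus2LL_full -2 log likelihoods of the nested
#'   (reduced) and extended (full) models.
#' @param df Number of added parameters.
#' @param tolerance Allowed negative difference (Monte-Carlo slack) before
#'   the pair is rejected as inconsistent.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
lrt <- function(minus2LL_reduced, minus2LL_full, df, tolerance = 1e-6) {
  if (df < 1) abort_invalid("df must be >= 1")
  d <- as.numeric(minus2LL_reduced) - as.numeric(minus2LL_full)
  if (d < -tolerance)
    abort_invalid(sprintf(
      "full-model -2LL exceeds reduced-model -2LL by %.3g (beyond tolerance)", -d))
  d <- max(d, 0)
  list(statistic = d, df = df, p_value = pchisq(d, df, lower.tail = FALSE))
}

#' Conditional standardized residuals
#'
#' `(observed - conditional prediction) / (sigma * conditional prediction)`
#' per observation, alongside the corresponding population-prediction
#' residuals.
#'
#' @param fit An [em_fit()] result.
#' @param dataset The fitted dataset.
#' @return Data frame with one row per observation.
#' @export
conditional_std_residuals <- function(fit, dataset) {
  stopifnot(inherits(fit, "mm_fit"))
  sigma <- fit$pop$sigma_prop
  out <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    b <- fit$conditional_mean_log[s$subject_id, ]
    m <- individual_mean_log(fit$pop, s$covariates)
    fc <- simulate_glucose(exp(b), s$dose, s$Gbasal, s$Ibasal, s$forcing,
                           s$obs_times, fit$settings$ode_rtol, fit$settings$ode_atol)
    fp <- simulate_glucose(exp(m), s$dose, s$Gbasal, s$Ibasal, s$forcing,
                           s$obs_times, fit$settings$ode_rtol, fit$settings$ode_atol)
    out[[i]] <- data.frame(subject_id = s$subject_id, time = s$obs_times,
                           observed = s$obs_glucose,
                           pred_conditional = fc, pred_population = fp,
                           residual = (s$obs_glucose - fc) / (sigma * fc),
                           residual_population = (s$obs_glucose - fp) / (sigma * fp))
  }
  do.call(rbind, out)
}

#' Relative standard errors of the population estimates
#'
#' Scores of the marginal likelihood are assembled from E-step conditional
#' moments via the Fisher/Louis identity (the score of the marginal equals
#' the conditional expectation of the complete-data score); the observed
#' information is estimated by the outer product of per-subject scores. A
#' nonparametric subject bootstrap is available as a fallback.
#'
#' @param fit An [em_fit()] result.
#' @param dataset The fitted dataset.
#' @param settings Settings (defaults to the fit's).
#' @param method `"opg"` (outer product of scores, default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `method = "bootstrap"`.
#' @return List with `rse` (RSE-CV% per estimate), `se`, `vcov` and
#'   `singular`.
#' @export
standard_errors <- function(fit, dataset, settings = fit$settings,
                            method = c("opg", "bootstrap"), n_boot = 20) {
  stopifnot(inherits(fit, "mm_fit"))
  method <- match.arg(method)
  if (method == "bootstrap") return(se_bootstrap(fit, dataset, settings, n_boot))
  effects <- fit$spec
  p <- length(effects)
  beta <- fit$beta
  Sigma <- fit$pop$Sigma_log
  sigma <- fit$pop$sigma_prop
  W <- solve(Sigma)
  lt <- which(lower.tri(Sigma, diag = TRUE), arr.ind = TRUE)
  nS <- nrow(lt)
  n <- length(dataset)
  Sc <- matrix(0, n, 4 + p + nS + 1)
  for (i in seq_len(n)) {
    s <- dataset[[i]]
    A_i <- cbind(diag(4), effects_design(effects, s$covariates))
    m_i <- drop(A_i %*% beta)
    r <- estep_subject(s, m_i, Sigma, sigma, settings, mode0 = m_i,
                       seed = derive_seed(settings$seed, s$subject_id, "se"),
                       n_samples = 2L * settings$n_importance_samples,
                       optim_maxit = 40)
    if (is.null(r))
      abort_numerical(sprintf("score evaluation failed for subject %s", s$subject_id))
    resid <- r$mean - m_i
    Euu <- r$cov + tcrossprod(resid)
    Sc[i, seq_len(4 + p)] <- drop(t(A_i) %*% W %*% resid)
    Mh <- 0.5 * (W %*% Euu %*% W - W)
    sS <- numeric(nS)
    for (q in seq_len(nS)) {
      j <- lt[q, 1]; k <- lt[q, 2]
      sS[q] <- if (j == k) Mh[j, j] else 2 * Mh[j, k]
    }
    Sc[i, 4 + p + seq_len(nS)] <- sS
    Sc[i, 4 + p + nS + 1] <- -r$n_obs / sigma + r$essr / sigma^3
  }
  info <- crossprod(Sc)
  singular <- FALSE
  V <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) < 0)) {
    warning("information matrix is singular or indefinite; using pseudo-inverse ",
            "(consider method = \"bootstrap\")")
    singular <- TRUE
    V <- pracma::pinv(info)
  }
  se_all <- sqrt(pmax(diag(V), 0))

  rse <- c()
  se_out <- c()
  for (k in 1:4) {
    rse[paste0("TV_", MM_PARS[k])] <- 100 * se_all[k]
    se_out[paste0("TV_", MM_PARS[k])] <- exp(beta[k]) * se_all[k]
  }
  if (p > 0) {
    for (j in seq_len(p)) {
      e <- effects[[j]]
      g <- beta[4 + j]
      se_g <- se_all[4 + j]
      lab <- effect_label(e)
      if (e$kind == "proportional_shift") {
        phi <- expm1(g)
        se_out[lab] <- exp(g) * se_g
        rse[lab] <- 100 * exp(g) * se_g / abs(phi)
      } else {
        se_out[lab] <- se_g
        rse[lab] <- 100 * se_g / abs(g)
      }
    }
  }
  for (q in seq_len(nS)) {
    j <- lt[q, 1]; k <- lt[q, 2]
    if (j == k) {
      lab <- paste0("IIV_", MM_PARS[j])
      se_S <- se_all[4 + p + q]
      se_out[lab] <- se_S
      rse[lab] <- 100 * se_S / (2 * Sigma[j, j])
    }
  }
  se_out["sigma_prop"] <- se_all[4 + p + nS + 1]
  rse["sigma_prop"] <- 100 * se_all[4 + p + nS + 1] / sigma
  list(rse = rse, se = se_out, vcov = V, singular = singular)
}

# nonparametric subject bootstrap (short warm-started refits)
se_bootstrap <- function(fit, dataset, settings, n_boot) {
  n <- length(dataset)
  bs <- settings
  bs$max_iterations <- min(settings$max_iterations, 8L)
  ests <- matrix(NA_real_, n_boot, length(fit$beta) + 1)
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(settings$seed, "boot", b))
    idx <- sample.int(n, n, replace = TRUE)
    ds <- dataset[idx]
    for (k in seq_along(ds)) {  # ids must stay unique for seeding
      ds[[k]]$subject_id <- paste0(ds[[k]]$subject_id, "#", k)
    }
    bs$seed <- derive_seed(settings$seed, "bootfit", b)
    fb <- tryCatch(
      suppressWarnings(em_fit(ds, spec = fit$spec, init = fit$pop, settings = bs)),
      error = function(e) NULL)
    if (!is.null(fb)) ests[b, ] <- c(fb$beta, fb$pop$sigma_prop)
  }
  ok <- stats::complete.cases(ests)
  if (sum(ok) < 3) abort_numerical("bootstrap standard errors failed (too few successful refits)")
  se_all <- apply(ests[ok, , drop = FALSE], 2, sd)
  est <- c(fit$beta, fit$pop$sigma_prop)
  rse <- 100 * se_all / abs(est)
  names(rse) <- c(names(fit$beta), "sigma_prop")
  list(rse = rse, se = setNames(se_all, names(rse)), vcov = NULL,
       singular = FALSE, n_success = sum(ok))
}
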
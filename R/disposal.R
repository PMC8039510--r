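# Partitioning of net glucose disposal into non-insulin-dependent and
# insulin-dependent components:
#   GD_NID = integral of GEZI * G(t) over [0, T]
#   GD_ID  = integral of X(t) * G(t) over [0, T]
# with T the subject's last measurement time, plus the basal-state fraction
# GEZI / (GEZI + SI * Ibasal) and cohort-level summaries.

#' Basal non-insulin-dependent disposal fraction
#'
#' @param GEZI Glucose effectiveness at zero insulin (1/min), > 0.
#' @param SI Insulin sensitivity (1/min per pmol/L), >= 0.
#' @param Ibasal Basal insulin (pmol/L), >= 0.
#' @return `GEZI / (GEZI + SI * Ibasal)`, in (0, 1]. Vectorized.
#' @export
basal_noninsulin_fraction <- function(GEZI, SI, Ibasal) {
  if (any(GEZI <= 0)) abort_invalid("GEZI must be > 0")
  if (any(SI < 0) || any(Ibasal < 0)) abort_invalid("SI and Ibasal must be >= 0")
  GEZI / (GEZI + SI * Ibasal)
}

#' Dynamic disposal integrals for one subject
#'
#' Simulates the minimal model at the given parameters over the subject's
#' test and integrates `GEZI * G(t)` and `X(t) * G(t)` by the trapezoid rule
#' on a uniform grid from 0 to the last observation time.
#'
#' @param params An [mm_params()] vector (typically the subject's
#'   conditional-mean estimates).
#' @param subject A [subject_data()] object.
#' @param grid_step Integration grid step in minutes (default 0.1).
#' @return One-row data.frame: `GD_NID`, `GD_ID` (mmol/L * min),
#'   `fraction_NID`, `T_end`.
#' @export
disposal_integrals <- function(params, subject, grid_step = 0.1) {
  stopifnot(inherits(subject, "subject_data"))
  th <- unclass(params)[MM_PARS]
  T_end <- max(subject$obs_times)
  grid <- seq(0, T_end, by = grid_step)
  if (grid[length(grid)] < T_end) grid <- c(grid, T_end)
  st <- simulate_glucose(params, subject$dose, subject$Gbasal, subject$Ibasal,
                         subject$forcing, grid, return_state = TRUE)
  gd_nid <- pracma::trapz(grid, th[["GEZI"]] * st$G)
  gd_id <- pracma::trapz(grid, st$X * st$G)
  data.frame(subject_id = subject$subject_id,
             GD_NID = gd_nid, GD_ID = gd_id,
             fraction_NID = gd_nid / (gd_nid + gd_id),
             T_end = T_end)
}

#' Cohort summary of disposal fractions
#'
#' @param fractions Numeric vector of per-subject fractions in `[0, 1]`.
#' @param group Grouping vector (e.g. cohort ND/T2D) of the same length.
#' @return Data frame per group: `n`, `mean_pct`, `sd_pct`, `min_pct`,
#'   `max_pct` (fractions expressed in percent).
#' @export
cohort_fraction_summary <- function(fractions, group) {
  if (length(fractions) != length(group))
    abort_invalid("fractions and group must have equal length")
  if (length(fractions) == 0) abort_invalid("empty input")
  g <- factor(group)
  cnt <- table(g)
  if (any(cnt < 2))
    abort_invalid(paste0("groups with fewer than 2 subjects: ",
                         paste(names(cnt)[cnt < 2], collapse = ", ")))
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    x <- 100 * fractions[g == lev]
    data.frame(group = lev, n = length(x), mean_pct = mean(x),
               sd_pct = sd(x), min_pct = min(x), max_pct = max(x))
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact permutation enumeration when both groups have at most 10
#' observations (midranks for ties); otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 4 for the
#'   intended use; smaller inputs are allowed for the exact mode).
#' @param exact Force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default chooses by group size.
#' @return List with `statistic` (Mann-Whitney U of `group_a`), `p_value`
#'   and `method`.
#' @export
rank_sum_test <- function(group_a, group_b, exact = NULL) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 1 || nb < 1) abort_invalid("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  N <- na + nb
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (length(unique(pooled)) == 1) {
    warning("all values tied across both groups; p = 1")
    return(list(statistic = U, p_value = 1, method = "degenerate"))
  }
  if (is.null(exact)) exact <- (na <= 10 && nb <= 10)
  if (exact) {
    idx <- combn(N, na)
    Us <- colSums(matrix(rk[idx], nrow = na)) - na * (na + 1) / 2
    p_lo <- mean(Us <= U + 1e-9)
    p_hi <- mean(Us >= U - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = U, p_value = p, method = "exact enumeration"))
  }
  mu <- na * nb / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sig2 <- na * nb / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sig2 <= 0) {
    warning("zero rank variance; p = 1")
    return(list(statistic = U, p_value = 1, method = "normal approximation"))
  }
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  list(statistic = U, p_value = min(1, 2 * pnorm(-abs(z))),
       method = "normal approximation (tie-corrected)")
}
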
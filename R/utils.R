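# Internal helpers: typed conditions, seeds, small numerics.

mm_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "mmpop_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_invalid <- function(msg) mm_abort(msg, "mmpop_invalid_argument")
abort_numerical <- function(msg) mm_abort(msg, "mmpop_numerical_error")
abort_data <- function(msg) mm_abort(msg, "mmpop_data_error")
abort_config <- function(msg) mm_abort(msg, "mmpop_configuration_error")
abort_parse <- function(msg) mm_abort(msg, "mmpop_parse_error")
abort_insufficient <- function(msg) mm_abort(msg, "mmpop_data_insufficiency")

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log density of rows of X under N(mean, Sigma)
dmvnorm_log_rows <- function(X, mean, Sigma) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  L <- chol(Sigma)
  Z <- backsolve(L, t(X) - mean, transpose = TRUE)
  -0.5 * colSums(Z^2) - sum(log(diag(L))) - 0.5 * ncol(X) * log(2 * pi)
}

# deterministic 31-bit hash of strings/numbers for sub-seed derivation
hash_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                    character(1)), collapse = "/")
  h <- 216613
  for (b in utf8ToInt(s)) {
    h <- (h * 131 + b) %% 1964987
  }
  h
}

derive_seed <- function(seed, ...) {
  as.integer((abs(seed) * 1009 + hash_seed(...)) %% 2147483629L)
}

# symmetrize and floor eigenvalues so a covariance stays SPD
make_spd <- function(S, floor = 1e-10) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, floor)
  S2 <- e$vectors %*% (lam * t(e$vectors))
  (S2 + t(S2)) / 2
}

is_spd <- function(S, tol = 1e-10) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) return(FALSE)
  all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > tol)
}

# truncated-normal sampler whose *truncated* mean matches `mean`
rtnorm_matched <- function(n, mean, sd, lo, hi) {
  trunc_mean <- function(m) {
    a <- (lo - m) / sd
    b <- (hi - m) / sd
    Z <- pnorm(b) - pnorm(a)
    m + sd * (dnorm(a) - dnorm(b)) / Z
  }
  f <- function(m) trunc_mean(m) - mean
  m_star <- tryCatch(
    uniroot(f, lower = mean - 3 * sd, upper = mean + 3 * sd, tol = 1e-8)$root,
    error = function(e) abort_config(sprintf(
      "infeasible truncation bounds [%g, %g] for target mean %g (sd %g)",
      lo, hi, mean, sd))
  )
  p <- runif(n, pnorm(lo, m_star, sd), pnorm(hi, m_star, sd))
  qnorm(p, m_star, sd)
}

#' @importFrom stats uniroot
NULL

# FNV-style hash of an R object, used to stamp pipeline artifacts
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
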
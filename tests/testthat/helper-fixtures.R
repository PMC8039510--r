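# Shared fixtures built in code.

# constant-insulin forcing at a given level
const_forcing <- function(level = 40, t_end = 360) {
  insulin_forcing(c(0, t_end), c(level, level), Ibasal = level)
}

# a biphasic forcing with a realistic first-phase peak
biphasic_forcing <- function(Ib = 40, t_end = 180) {
  tk <- c(0, 2, 4, 6, 8, 10, 15, 20, 30, 45, 60, 90, 120, 150, t_end)
  ck <- Ib + 450 * (1 - exp(-tk / 1.2)) * exp(-tk / 12) +
    100 * (1 - exp(-tk / 15)) * exp(-tk / 45)
  insulin_forcing(tk, ck, Ibasal = Ib)
}

ref_params <- function() mm_params(GEZI = 0.02, SI = 5e-5, p2 = 0.04, V = 12)

# small noiseless subject simulated from given params
make_subject <- function(id = "X1", params = ref_params(), Gb = 5, Ib = 40,
                         dose = 124.89, forcing = biphasic_forcing(Ib),
                         times = c(5, 8, 12, 16, 22, 30, 40, 60, 90, 120, 150, 180),
                         sigma = 0, seed = 1, covariates = list(T2D = 0, IM = 0)) {
  f <- simulate_glucose(params, dose, Gb, Ib, forcing, times)
  if (sigma > 0) {
    set.seed(seed)
    f <- f * (1 + sigma * rnorm(length(f)))
  }
  subject_data(id, "IVGTT", dose, times, f, forcing, Gbasal = Gb, Ibasal = Ib,
               covariates = covariates)
}

# compact settings for fast fits in tests
quick_settings <- function(seed = 1, ...) {
  fit_settings(n_importance_samples = 50, max_iterations = 10,
               convergence_rtol = 5e-3, seed = seed, ...)
}

# small cohort of noiseless-ish subjects at a common parameter vector
make_dataset <- function(n = 10, params = ref_params(), sigma = 1e-4,
                         seed = 42) {
  lapply(seq_len(n), function(i) {
    make_subject(sprintf("D%02d", i), params = params, sigma = sigma,
                 seed = seed + i)
  })
}
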
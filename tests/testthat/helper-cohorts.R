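# Simulated cohorts are built once per test run and shared across test files.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(config)
  }
  .cohort_cache[[key]]
}

# The 50-participant ideal-Bayes reference cohort (experiment 1, serial).
ideal_exp1_cohort <- function() {
  cached_cohort("ideal_exp1", cohort_config(
    n_participants = 50, experiment = "exp1", group = "serial",
    strategy = "bayes", motor_sd = 0.005, seed = 101
  ))
}

# Likelihood-only linear learners: weights depend on likelihood precision
# alone, anchored to the empirical slope medians of the interpolation
# protocol (0.98 for the narrow, 0.87 for the wide likelihood).
lo_linear_coeffs <- function(sigma_Ln = 0.024, sigma_Lw = 0.15,
                             w_Ln = 0.98, w_Lw = 0.87) {
  b2 <- (w_Ln - w_Lw) / (1 / sigma_Ln^2 - 1 / sigma_Lw^2)
  b0 <- w_Lw - b2 / sigma_Lw^2
  c(b0, 0, b2)
}
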
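test_that("centroid responses are the dot mean plus motor noise", {
  d <- coin_task_design("exp1")
  quiet <- ideal_observer(d, motor_sd = 0)
  expect_equal(respond_likelihood_only(quiet, mean(c(-0.02, -0.01, 0, 0.01, 0.02))), 0)
  expect_equal(respond_likelihood_only(quiet, mean(c(0.1, 0.1, 0.1, 0.1, 0.2))), 0.12)
  noisy <- ideal_observer(d, motor_sd = 0.02)
  set.seed(21)
  r <- respond_likelihood_only(noisy, rep(0.05, 1e4))
  expect_lt(abs(var(r) / 4e-4 - 1), 0.1)
})

test_that("noiseless strategy responses match their defining weights exactly", {
  d <- coin_task_design("exp1")
  set.seed(22)
  tr <- sample_trials(d, "Pw", "Ln", 50)
  w <- optimal_slope(0.085, 0.06, 5)
  bayes <- ideal_observer(d, motor_sd = 0)
  expect_equal(respond_coin(bayes, tr, d), w * tr$mu_L, tolerance = 1e-12)

  lik <- ideal_observer(d, strategy = "likelihood_only", motor_sd = 0)
  expect_equal(respond_coin(lik, tr, d), tr$mu_L)
  pri <- ideal_observer(d, strategy = "prior_only", motor_sd = 0)
  expect_equal(respond_coin(pri, tr, d), rep(0, nrow(tr)))

  lin <- ideal_observer(d, strategy = "linear_map", motor_sd = 0,
                        linear_coeffs = c(0.2, 0, 1e-3))
  w_lin <- min(max(0.2 + 1e-3 / 0.06^2, 0), 1)
  expect_equal(respond_coin(lin, tr, d), w_lin * tr$mu_L, tolerance = 1e-12)
})

test_that("noiseless slopes recover the generating weight to high precision", {
  d <- coin_task_design("exp1")
  set.seed(23)
  tr <- sample_trials(d, "Pw", "Ln", 200)
  bayes <- ideal_observer(d, motor_sd = 0)
  fit <- fit_slope(tr$mu_L, respond_coin(bayes, tr, d))
  expect_equal(fit$slope, optimal_slope(0.085, 0.06, 5), tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)

  lik <- ideal_observer(d, strategy = "likelihood_only", motor_sd = 0)
  expect_equal(fit_slope(tr$mu_L, respond_coin(lik, tr, d))$slope, 1)
  pri <- ideal_observer(d, strategy = "prior_only", motor_sd = 0)
  expect_equal(fit_slope(tr$mu_L, respond_coin(pri, tr, d))$slope, 0)
})

test_that("exemplar estimation behaves as self-normalized importance sampling", {
  expect_equal(exemplar_estimate(0.03, mu_L = -0.4, 0.06, 10), 0.03)
  expect_equal(exemplar_estimate(0.03, mu_L = 0.2, 0.06, 1), 0.03)
  expect_error(exemplar_estimate(numeric(0), 0, 0.06, 5), "empty")

  set.seed(24)
  mem <- rnorm(2e4, 0, 0.085)
  w <- 0.085^2 / (0.085^2 + 0.06^2)
  est <- exemplar_estimate(mem, 0.1, 0.06, 2e4)
  expect_lt(abs(est - w * 0.1), 0.05 * 0.085)

  # sampling variability shrinks with N
  reps <- function(n) replicate(50, exemplar_estimate(mem, 0.1, 0.06, n))
  expect_lt(var(reps(500)), var(reps(5)))
})

test_that("rote observers reuse the trained weight, nulling the slope change", {
  d <- coin_task_design("exp1")
  obs <- ideal_observer(d, strategy = "rote", motor_sd = 0)
  set.seed(25)
  tt <- simulate_participant(obs, d, "serial", counterbalance = 2, "P001")
  est <- estimate_participants(tt)
  row <- est[!is.na(est$new_likelihood_label), ]
  expect_equal(row$measured_slope_new, row$slope_learned, tolerance = 1e-10)

  lone <- observer_spec("rote", internal_sigma_P = c(Pw = 0.085),
                        internal_sigma_L = c(Ln = 0.06, Lw = 0.15), motor_sd = 0)
  stray <- sample_trials(d, "Pn", "Ln", 3)
  expect_error(
    respond_coin(lone, stray, d,
                 trained = data.frame(prior_label = "Pw", likelihood_label = "Ln")),
    "no trained combination"
  )
})

test_that("simulated sessions have the right shape and hit rule", {
  d <- coin_task_design("exp1")
  obs <- ideal_observer(d)
  set.seed(26)
  tt <- simulate_participant(obs, d, "serial", 1, "P007")
  expect_equal(nrow(tt), 80L + 400L + 180L)
  expect_equal(sum(tt$phase == "likelihood_only"), 80L)
  coin <- tt[tt$phase != "likelihood_only", ]
  expect_equal(coin$hit, abs(coin$response_x - coin$coin_x) <= 0.015)
  expect_false(any(is.na(coin$response_x)))
})

test_that("cohorts are reproducible and miscalibration shifts slopes as expected", {
  cfg <- cohort_config(n_participants = 3, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$participants, b$participants)

  # believing the likelihood is tighter than it is -> over-reliance on it
  over <- simulate_cohort(cohort_config(n_participants = 4, group = "parallel",
                                        bias_L = 0.7, motor_sd = 0.001, seed = 31))
  est <- estimate_participants(over$trials)
  opt <- optimal_slope(prior_sd <- ifelse(est$prior_label == "Pn", 0.025, 0.085),
                       ifelse(est$likelihood_label == "Ln", 0.06, 0.15), 5)
  expect_true(all(est$slope_learned > opt))
})
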
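test_that("slope fitting matches closed-form least squares", {
  x <- seq(-0.2, 0.2, length.out = 40)
  fit <- fit_slope(x, 0.5 * x)
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 0)
  expect_equal(fit_slope(x, x)$slope, 1)

  # through-origin variant: beta = sum(xy) / sum(x^2), not the free-fit slope
  xa <- seq(0.05, 0.3, length.out = 30)
  y <- 0.7 * xa + 0.01
  fit0 <- fit_slope(xa, y, zero_intercept = TRUE)
  expect_equal(fit0$slope, sum(xa * y) / sum(xa^2))
  expect_equal(fit0$intercept, 0)
  expect_false(isTRUE(all.equal(fit0$slope, 0.7)))

  # slopes ignore constant response shifts when the intercept is free
  set.seed(41)
  yn <- 0.6 * x + rnorm(40, 0, 0.01)
  expect_equal(fit_slope(x, yn)$slope, fit_slope(x, yn + 0.3)$slope)

  # discarding drops the first k trials in presentation order
  y2 <- c(rep(10, 5), 0.5 * x[-(1:5)])
  expect_equal(fit_slope(x, y2, discard = 5)$slope, 0.5)
  expect_equal(fit_slope(x, y2, discard = 5)$n_used, 35L)
  expect_error(fit_slope(x[1:3], y2[1:3], discard = 2, condition = "PnLn"), "PnLn")
})

test_that("likelihood variance proxy is the population mean squared deviation", {
  expect_equal(sigma_li_sq(1:10 / 10, 1:10 / 10), 0)
  expect_equal(sigma_li_sq(1:10 / 10 + 0.01, 1:10 / 10), 1e-4)
  expect_error(sigma_li_sq(numeric(0), numeric(0)), "no trials")

  # noiseless centroid observer: proxy converges to sigma_L^2 / n_dots
  d <- coin_task_design("exp1")
  set.seed(42)
  lo <- sample_trials(d, "Pw", "Ln", 1e4)
  expect_lt(abs(sigma_li_sq(lo$mu_L, lo$coin_x) / (0.06^2 / 5) - 1), 0.05)
})

test_that("prior variance proxy inverts the weighting relation", {
  expect_equal(sigma_pi_sq(0.001, 0.5), 0.001)
  s <- optimal_slope(0.025, 0.06, 5)
  expect_equal(sigma_pi_sq(0.06^2 / 5, s), 0.025^2, tolerance = 1e-12)
  expect_true(is.na(sigma_pi_sq(7.2e-4, 0.999)))
  expect_true(is.na(sigma_pi_sq(7.2e-4, -0.1)))
  expect_error(sigma_pi_sq(-1, 0.5), "positive")
})

test_that("optimal weights match direct arithmetic on the design values", {
  expect_equal(optimal_slope(0.085, 0.06, 5), 0.90938, tolerance = 1e-4)
  expect_equal(optimal_slope(0.025, 0.15, 5), 0.12195, tolerance = 1e-4)
  expect_equal(optimal_slope(0.1, 0), 1)
  expect_error(optimal_slope(0, 0.06), "positive")
})

test_that("prediction and inversion are mutual inverses on (0, 1)", {
  for (s in seq(0.02, 0.98, by = 0.06)) {
    for (v in c(1e-4, 7.2e-4, 4.5e-3)) {
      expect_equal(predicted_transfer_slope(sigma_pi_sq(v, s), v), s,
                   tolerance = 1e-12)
    }
  }
})

test_that("the estimation chain recovers an ideal participant end to end", {
  d <- coin_task_design("exp1")
  set.seed(43)
  tt <- simulate_participant(ideal_observer(d, motor_sd = 0), d, "serial", 2, "P001")
  est <- estimate_participants(tt)
  expect_equal(nrow(est), 2L)
  # noiseless observer: learned slopes equal the optimal weights exactly
  opt <- optimal_slope(ifelse(est$prior_label == "Pn", 0.025, 0.085),
                       ifelse(est$likelihood_label == "Ln", 0.06, 0.15), 5)
  expect_equal(est$slope_learned, opt, tolerance = 1e-10)
  row <- est[!is.na(est$new_likelihood_label), ]
  expect_equal(row$prior_label, "Pw")  # counterbalance 2 transfers the wide prior
  expect_equal(row$new_likelihood_label, "Ln")
  expect_equal(row$measured_slope_new, optimal_slope(0.085, 0.06, 5),
               tolerance = 1e-10)
})
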
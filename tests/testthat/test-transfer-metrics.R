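test_that("transfer score normalizes measured by predicted slope change", {
  expect_equal(transfer_score(0.8, 0.6, 0.9), 0.2 / 0.3)
  expect_equal(transfer_score(0.7, 0.5, 0.7), 1)   # measured = predicted
  expect_equal(transfer_score(0.5, 0.5, 0.8), 0)   # measured = learned
  expect_true(is.na(transfer_score(0.5, 0.6, 0.6 + 1e-9)))  # undefined change
})

test_that("experiment 2 scores pool the two per-combination values", {
  est <- tibble::tibble(
    participant_id = "P001", experiment = "exp2", group = "interpolation",
    prior_label = "Pw", likelihood_label = c("Ln", "Lw"),
    slope_learned = c(0.95, 0.60),
    sigma_li_sq = c(2e-4, 5e-3), sigma_pi_sq = c(1e-3, 2e-3), reliable = TRUE,
    slope_transfer_old = c(0.95, 0.60),
    new_likelihood_label = "Lm", sigma_li_sq_new = 8e-4,
    predicted_slope = c(0.80, 0.75), measured_slope_new = 0.78
  )
  sc <- transfer_scores(est)
  ts1 <- (0.78 - 0.95) / (0.80 - 0.95)
  ts2 <- (0.78 - 0.60) / (0.75 - 0.60)
  expect_equal(sc$ts, mean(c(ts1, ts2)))
  expect_equal(sc$n_combos, 2L)
  sc2 <- transfer_scores(est, pooling = "ratio_of_changes")
  expect_equal(sc2$ts, ((0.78 - 0.95) + (0.78 - 0.60)) /
                        ((0.80 - 0.95) + (0.75 - 0.60)))
  # an unreliable combination drops out of the pool
  est$predicted_slope[1] <- NA
  expect_equal(transfer_scores(est)$ts, ts2)
})

test_that("posterior parameters satisfy the Gaussian-product identities", {
  p <- posterior_params(0.1, 0.085, 0.15, 5)
  w <- optimal_slope(0.085, 0.15, 5)
  expect_equal(p$mean, w * 0.1)
  # posterior variance = (1 - w) * prior variance, an independent identity
  expect_equal(p$sd^2, (1 - w) * 0.085^2, tolerance = 1e-12)
  expect_equal(posterior_params(0, 0.025, 0.06)$mean, 0)
  # flat-prior limit: mean -> centroid, variance -> sigma_L^2 / n
  p2 <- posterior_params(0.1, 1e6, 0.15, 5)
  expect_equal(p2$mean, 0.1, tolerance = 1e-6)
  expect_equal(p2$sd^2, 0.15^2 / 5, tolerance = 1e-6)
})

test_that("hit probability matches numerical integration of the posterior", {
  expect_equal(p_hit(0, 0, 0.015, 0.03), 2 * pnorm(1) - 1)
  for (prm in list(c(0.01, 0.0, 0.015), c(-0.02, 0.01, 0.05))) {
    num <- integrate(dnorm, prm[1] - 0.015, prm[1] + 0.015,
                     mean = prm[2], sd = prm[3])$value
    expect_equal(p_hit(prm[1], prm[2], prm[3], 0.03), num, tolerance = 1e-8)
  }
  expect_equal(p_hit(10, 0, 0.015, 0.03), 0)
  expect_equal(p_hit(0.007, 0, 0.02, 0.03), p_hit(-0.007, 0, 0.02, 0.03))
})

test_that("optimality index peaks at the posterior mean and decays monotonically", {
  expect_equal(optimality_index(0.02, 0.02, 0.01, 0.03), 1)
  xs <- seq(0, 0.1, by = 0.005)
  oi <- optimality_index(0.02 + xs, 0.02, 0.01, 0.03)
  expect_true(all(diff(oi) < 0))
  expect_equal(oi, optimality_index(0.02 - xs, 0.02, 0.01, 0.03))
})

test_that("a static observer shows no optimality drift across the transfer phase", {
  d <- coin_task_design("exp1")
  cohort <- simulate_cohort(cohort_config(n_participants = 12, seed = 51))
  oi <- trial_optimality(cohort$trials, d)
  new_tr <- oi[oi$phase == "transfer" & oi$novelty == "new", ]
  drift <- vapply(split(new_tr, new_tr$participant_id), function(g) {
    g <- g[order(g$trial_index), ]
    mean(g$optimality[1:10]) - mean(g$optimality[(nrow(g) - 9):nrow(g)])
  }, numeric(1))
  expect_lt(abs(mean(drift)), 0.1)
  expect_true(all(oi$optimality <= 1))
})

test_that("MAD screening flags gross outliers, little else, and is idempotent", {
  keep <- mad_filter(c(1, 1, 1, 100))
  expect_equal(as.logical(keep), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(attr(keep, "n_excluded"), 1L)

  set.seed(52)
  v <- rnorm(1000)
  k <- mad_filter(v)
  expect_lt(attr(k, "n_excluded") / 1000, 0.02)
  k2 <- mad_filter(v[k])
  expect_lt(attr(k2, "n_excluded") / sum(k), 0.01)
  expect_error(mad_filter(c(1, 2)), "at least 3")
})

test_that("staged screening reports exclusions without distorting clean cohorts", {
  cohort <- ideal_exp1_cohort()
  an <- transfer_analysis(cohort$trials)
  expect_s3_class(an$scores, "tbl_df")
  expect_equal(nrow(an$scores), 50L)
  kept <- an$scores[!an$scores$excluded, ]
  expect_gte(nrow(kept), 40L)
  expect_lt(abs(mean(kept$ts) - 1), 0.1)
  expect_true(all(c("experiment", "group", "n", "mean_ts", "median_ts", "iqr_ts")
                  %in% names(an$summary)))
})
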
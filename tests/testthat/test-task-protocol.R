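test_that("experiment 1 schedules deliver the printed per-condition trial counts", {
  d <- coin_task_design("exp1")
  set.seed(11)
  for (grp in c("serial", "parallel")) {
    for (cb in 1:4) {
      s <- build_schedule(d, grp, cb)
      learn <- s[s$phase == "learning", ]
      trans <- s[s$phase == "transfer", ]
      expect_equal(nrow(learn), 400L)
      expect_equal(nrow(trans), 180L)
      combo <- paste(learn$prior_label, learn$likelihood_label)
      expect_true(all(table(combo) == 200L))
      # orthogonal assignment: each prior and each likelihood trained once
      expect_setequal(unique(learn$prior_label), c("Pn", "Pw"))
      expect_setequal(unique(learn$likelihood_label), c("Ln", "Lw"))
      # transfer: one prior crossed with both likelihoods, 90 each
      expect_length(unique(trans$prior_label), 1L)
      expect_true(all(table(trans$likelihood_label) == 90L))
      expect_setequal(unique(trans$novelty), c("old", "new"))
    }
  }
  s <- build_schedule(d, "serial", 1)
  first200 <- paste(s$prior_label, s$likelihood_label)[1:200]
  expect_length(unique(first200), 1L)
})

test_that("experiment 2 schedules train the right pairs and tag the novel one", {
  d <- coin_task_design("exp2")
  set.seed(12)
  s <- build_schedule(d, "interpolation")
  learn <- s[s$phase == "learning", ]
  trans <- s[s$phase == "transfer", ]
  expect_equal(nrow(learn), 200L)
  expect_setequal(unique(learn$likelihood_label), c("Ln", "Lw"))
  expect_true(all(table(learn$likelihood_label) == 100L))
  expect_equal(nrow(trans), 225L)
  expect_true(all(table(trans$likelihood_label) == 75L))
  expect_equal(unique(trans$likelihood_label[trans$novelty == "new"]), "Lm")

  s2 <- build_schedule(d, "extrapolation")
  expect_setequal(unique(s2$likelihood_label[s2$phase == "learning"]), c("Ln", "Lm"))
  expect_equal(unique(s2$likelihood_label[s2$novelty %in% "new"]), "Lw")

  expect_error(build_schedule(d, "serial"), "group")
  expect_error(build_schedule(coin_task_design("exp1"), "interpolation"), "group")
  expect_error(build_schedule(coin_task_design("exp1"), "serial", 5), "counterbalance")
})

test_that("likelihood-only schedules match per-likelihood counts", {
  set.seed(13)
  lo1 <- build_likelihood_only_schedule(coin_task_design("exp1"))
  expect_equal(nrow(lo1), 80L)
  expect_true(all(table(lo1$likelihood_label) == 40L))
  lo2 <- build_likelihood_only_schedule(coin_task_design("exp2"))
  expect_equal(nrow(lo2), 90L)
  expect_true(all(table(lo2$likelihood_label) == 30L))
  expect_equal(sum(table(lo2$likelihood_label)), nrow(lo2))
})

test_that("interleaving never runs one condition for more than six trials", {
  d <- coin_task_design("exp1")
  set.seed(14)
  for (i in 1:5) {
    s <- build_schedule(d, "parallel", 1)
    runs <- rle(paste(s$prior_label, s$likelihood_label)[s$phase == "learning"])
    expect_lte(max(runs$lengths), 6L)
    truns <- rle(paste(s$prior_label, s$likelihood_label)[s$phase == "transfer"])
    expect_lte(max(truns$lengths), 6L)
  }
})

test_that("sampled trials follow the generative variances", {
  d <- coin_task_design("exp1")
  set.seed(15)
  tr <- sample_trials(d, "Pw", "Lw", 1e5)
  expect_lt(abs(var(tr$coin_x) / 0.085^2 - 1), 0.05)
  expect_lt(abs(var(tr$mu_L - tr$coin_x) / (0.15^2 / 5) - 1), 0.05)
})

test_that("a zero-dispersion likelihood puts every dot on the coin", {
  d <- coin_task_design("exp1")
  d$likelihoods$sigma[1] <- 0
  set.seed(16)
  tr <- sample_trials(d, "Pn", "Ln", 10)
  for (col in sprintf("dot_x%d", 1:5)) expect_equal(tr[[col]], tr$coin_x)
  expect_equal(tr$mu_L, tr$coin_x)
})

test_that("schedules are reproducible under a fixed seed", {
  d <- coin_task_design("exp2")
  set.seed(17); a <- build_schedule(d, "extrapolation")
  set.seed(17); b <- build_schedule(d, "extrapolation")
  expect_identical(a, b)
})

test_that("design validation rejects degenerate parameters and labels", {
  expect_error(coin_task_design("exp2", sigma_Ln_exp2 = 0), "positive")
  d <- coin_task_design("exp1")
  expect_equal(d$hit_window, d$net_width + d$coin_diameter)
  expect_error(sample_trials(d, "Px", "Ln", 5), "prior")
  expect_error(sample_trials(d, "Pn", "Lx", 5), "likelihood")
})
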
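# Engine-level properties: resampling, ESS, exactness on deterministic
# programs, unbiasedness, cross-engine agreement, Bayes factors.

test_that("resampling schemes have the right offspring distribution", {
  set.seed(1)
  expect_identical(resample(rep(1, 8), 8, "systematic"), 1:8)
  expect_identical(resample(c(1, 0), 5, "multinomial"), rep(1L, 5))
  w <- c(0.5, 0.3, 0.2)
  idx <- resample(w, 3e4, "multinomial")
  counts <- tabulate(idx, 3) / 3e4
  for (i in 1:3) {
    expect_within_3se(counts[i], w[i], sqrt(w[i] * (1 - w[i]) / 3e4))
  }
  expect_error(resample(c(0, 0), 2), "positive")
})

test_that("relative ESS matches its closed form", {
  expect_equal(relative_ess(rep(2, 10)), 1)
  expect_equal(relative_ess(c(5, 0, 0, 0, 0)), 1 / 5)
  expect_equal(relative_ess(c(2, 1, 1)), 16 / 18)
})

test_that("deterministic programs give exact log Z", {
  # pure birth with rho = 1 has deterministic weights at every checkpoint
  tr <- tree5()
  sp <- model_spec("CRB", fixed = list(lambda = 0.25))
  r <- run_smc(sp, tr, 10, seed = 1)
  expect_equal(r$log_z, crbd_loglik(tr, crbd_params(0.25, 0)), tolerance = 1e-12)
  r2 <- run_smc(sp, tr, 500, seed = 2)
  expect_equal(r$log_z, r2$log_z, tolerance = 1e-12)
})

test_that("Z is unbiased and independent of particle count", {
  tr <- tree3()
  sp <- model_spec("CRBD", fixed = list(lambda = 0.4, mu = 0.2))
  an <- exp(crbd_loglik(tr, crbd_params(0.4, 0.2)))
  runs <- 300
  set.seed(3)
  z100 <- exp(rep_logz("smc", sp, tr, 100, runs, 0))
  z500 <- exp(rep_logz("smc", sp, tr, 500, runs, 5000))
  expect_within_3se(mean(z100), an, sd(z100) / sqrt(runs))
  expect_within_3se(mean(z500), an, sd(z500) / sqrt(runs))
  expect_within_3se(mean(z100), mean(z500),
                    sqrt(var(z100) / runs + var(z500) / runs))
})

test_that("importance sampling: point-mass prior recovers the exact likelihood", {
  tr <- tree5()
  sp <- model_spec("CRBD", fixed = list(lambda = 0.2, mu = 0.1))
  r <- run_importance_sampling(sp, tr, 100, seed = 1)
  expect_equal(r$log_z, crbd_loglik(tr, crbd_params(0.2, 0.1)), tolerance = 1e-12)
  expect_error(run_importance_sampling(model_spec("ClaDS0"), tr, 10), "closed-form")
})

test_that("doubling importance-sampling particles halves the variance of Z", {
  tr <- tree3()
  sp <- model_spec("CRBD")
  set.seed(9)
  z1 <- exp(rep_logz("is", sp, tr, 400, 150, 0))
  z2 <- exp(rep_logz("is", sp, tr, 800, 150, 300))
  ratio <- var(z1) / var(z2)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.1)
})

test_that("all-dead checkpoints raise an estimator-failure error", {
  tr <- tree3()
  # lambda = 0 cannot produce the observed speciations: every particle dies
  # at the first internal-node factor, or earlier
  sp <- model_spec("CRBD", fixed = list(lambda = 0, mu = 0.5))
  expect_error(run_smc(sp, tr, 20, seed = 1), "dead at checkpoint")
})

test_that("log Bayes factors are antisymmetric and orientation-invariant", {
  tr <- tree3()
  spa <- model_spec("CRBD", fixed = list(lambda = 0.4, mu = 0.2))
  spb <- model_spec("CRB", fixed = list(lambda = 0.3))
  a <- run_smc(spa, tr, 100, seed = 1)
  b <- run_smc(spb, tr, 100, seed = 2)
  expect_equal(log_bayes_factor(a, b), -log_bayes_factor(b, a))
  a0 <- run_smc(spa, tr, 100, seed = 1, orientation = FALSE)
  b0 <- run_smc(spb, tr, 100, seed = 2, orientation = FALSE)
  expect_equal(log_bayes_factor(a, b), log_bayes_factor(a0, b0), tolerance = 1e-12)
  other <- run_smc(spb, tree5(), 100, seed = 3)
  expect_error(log_bayes_factor(a, other), "same tree")
})

test_that("aligned resampling does not inflate log Z variance", {
  tr <- tree20()
  sp <- model_spec("CRBD", fixed = list(lambda = 0.2, mu = 0.1), rho = 0.9)
  runs <- 60
  set.seed(13)
  aligned <- vapply(seq_len(runs), function(i) run_smc(sp, tr, 60)$log_z, 1)
  shuffled <- vapply(seq_len(runs), function(i) {
    divsmc:::run_smc_shuffled(sp, tr, 60)$log_z
  }, numeric(1))
  expect_lt(var(aligned), 1.05 * var(shuffled))
})
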
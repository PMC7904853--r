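# Alive-particle-filter properties: exact collapse to SMC without deaths,
# the unbiased inverse-binomial attempts correction, and failure behavior.

test_that("APF is bitwise identical to multinomial SMC on death-free programs", {
  tr <- tree5()
  # rho < 1 removes all deaths (survivors are weighted, not fatal)
  sp <- model_spec("CRBD", rho = 0.7, fixed = list(lambda = 0.3, mu = 0.1))
  for (seed in c(11, 12)) {
    a <- run_smc(sp, tr, 100, resampler = "multinomial", seed = seed)
    b <- run_apf(sp, tr, 100, seed = seed)
    expect_identical(a$log_z, b$log_z)
    expect_identical(a$weights, b$weights)
    expect_true(all(b$diagnostics$acceptance == 1))
  }
  # delayed generic path: tight rate priors keep hidden side branches small,
  # so no particle can die and the collapse must again be exact
  spd <- model_spec("CRBD", rho = 0.7,
                    priors = list(lambda = list(shape = 2, rate = 20),
                                  mu = list(shape = 2, rate = 20)))
  a <- run_smc(spd, tree3(), 80, resampler = "multinomial", seed = 21)
  b <- run_apf(spd, tree3(), 80, seed = 21)
  expect_true(all(b$diagnostics$acceptance == 1))
  expect_identical(a$log_z, b$log_z)
})

test_that("the attempts correction is the unbiased inverse-binomial estimator", {
  # single-checkpoint toy program: survival probability p, alive weight 1.
  # E[(N-1)/(A-1)] = p exactly for any N >= 2.
  p <- 0.5
  n <- 8
  reps <- 4000
  set.seed(31)
  est <- vapply(seq_len(reps), function(i) {
    collected <- 0L
    attempts <- 0L
    while (collected < n) {
      attempts <- attempts + 1L
      if (runif(1) < p) collected <- collected + 1L
    }
    (n - 1) / (attempts - 1)
  }, numeric(1))
  expect_within_3se(mean(est), p, sd(est) / sqrt(reps))
  # the engine reproduces this on a cherry where walks can die: a particle
  # survives a unit branch iff every hidden speciation's subtree leaves no
  # sampled tip, with probability exp(-lambda int (1 - E(t)) dt)
  ch <- read_newick("(A:1,B:1);")
  lam <- 0.5; mu <- 0.3
  spk <- model_spec("CRBD", fixed = list(lambda = lam, mu = mu))
  pcr <- crbd_params(lam, mu)
  p_alive <- exp(-lam * integrate(function(t) 1 - extinction_prob_crbd(pcr, t),
                                  0, 1)$value)
  set.seed(32)
  accs <- replicate(600, run_apf(spk, ch, n)$diagnostics$acceptance)
  inv <- (n - 1) / (n / accs[1, ] - 1)
  expect_within_3se(mean(inv), p_alive, sd(inv) / sqrt(length(inv)))
})

test_that("APF agrees with SMC in mean log Z when deaths occur", {
  tr <- tree3()
  sp <- model_spec("CRBD", fixed = list(lambda = 0.4, mu = 0.2))
  an <- exp(crbd_loglik(tr, crbd_params(0.4, 0.2)))
  runs <- 300
  set.seed(33)
  za <- exp(rep_logz("apf", sp, tr, 100, runs, 0))
  expect_within_3se(mean(za), an, sd(za) / sqrt(runs))
})

test_that("the attempts cap raises an estimator-failure error", {
  ch <- read_newick("(A:1,B:1);")
  # high turnover at rho = 1: nearly every propagation dies
  sp <- model_spec("CRBD", fixed = list(lambda = 12, mu = 6))
  expect_error(run_apf(sp, ch, 4, seed = 1, attempts_cap_factor = 3),
               "attempts")
})
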
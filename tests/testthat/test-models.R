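# Per-branch walk semantics, node and tip factors, hidden subtrees, and the
# corrections.

test_that("time-dependent rate follows the exponential decay law", {
  expect_equal(lambda_t(0.5, 0, 10, 3), 0.5)
  expect_equal(lambda_t(0.2, -0.1, 10, 0), 0.2 * exp(-1), tolerance = 1e-12)
  expect_equal(lambda_t(0.2, -0.1, 10, 10), 0.2)
  expect_error(lambda_t(0.2, -0.1, 10, 11), "t_ref")
})

test_that("ClaDS inheritance steps have the lognormal moments", {
  expect_equal(clads_child_rate(0.7, 0, 0), 0.7)
  set.seed(12)
  n <- 1e5
  la <- 0.4; log_alpha <- -0.3; s2 <- 0.09
  draws <- vapply(seq_len(n), function(i) clads_child_rate(la, log_alpha, s2), 1)
  steps <- log(draws) - log(la)
  expect_within_3se(mean(steps), log_alpha, sd(steps) / sqrt(n))
  ratio <- draws / la
  m <- exp(log_alpha + s2 / 2) # the rate multiplier of the original papers
  expect_within_3se(mean(ratio), m, sd(ratio) / sqrt(n))
  expect_error(clads_child_rate(0, 0, 0.1), "positive")
})

test_that("pure-birth walk conditions on zero hidden events", {
  sp <- model_spec("CRB", fixed = list(lambda = 0.3))
  st <- init_particle_state(sp, 5)
  r <- walk_branch(sp, st, 3, 1)
  expect_false(r$dead)
  expect_equal(r$dlw, -0.6, tolerance = 1e-12)
  r0 <- walk_branch(sp, st, 3, 3)
  expect_equal(r0$dlw, 0)
  expect_error(walk_branch(sp, st, 1, 3), "from_age")
})

test_that("hidden subtrees under pure birth with full sampling always kill", {
  sp <- model_spec("CRB", fixed = list(lambda = 0.5))
  st <- init_particle_state(sp, 5)
  set.seed(2)
  for (i in 1:20) {
    expect_true(hidden_subtree_outcome(sp, st, 4)$dead)
  }
})

test_that("hidden subtree with zero speciation rate is a pure death process", {
  # the side lineage never branches: it either goes extinct (weight 0) or
  # reaches the present, which under rho = 1 kills the particle with
  # probability exp(-mu t)
  sp <- model_spec("CRBD", fixed = list(lambda = 0, mu = 0.4))
  st <- init_particle_state(sp, 5)
  set.seed(3)
  reps <- 2000
  out <- vapply(seq_len(reps), function(i) {
    r <- hidden_subtree_outcome(sp, st, 6)
    if (!r$dead) expect_equal(r$dlw, 0)
    r$dead
  }, logical(1))
  p_reach <- exp(-0.4 * 6)
  expect_within_3se(mean(out), p_reach, sqrt(p_reach * (1 - p_reach) / reps))
})

test_that("hidden subtree survival frequency matches the extinction probability", {
  sp <- model_spec("CRBD", fixed = list(lambda = 1, mu = 0.5))
  st <- init_particle_state(sp, 10)
  set.seed(4)
  reps <- 4000
  alive <- mean(vapply(seq_len(reps), function(i) {
    !hidden_subtree_outcome(sp, st, 10)$dead
  }, logical(1)))
  E <- extinction_prob_crbd(crbd_params(1, 0.5), 10)
  expect_within_3se(alive, E, sqrt(E * (1 - E) / reps))
})

test_that("mean branch weight equals the analytic per-branch factor", {
  p <- crbd_params(1, 0.5)
  sp <- model_spec("CRBD", fixed = list(lambda = 1, mu = 0.5))
  st <- init_particle_state(sp, 10)
  set.seed(5)
  reps <- 8000
  w <- vapply(seq_len(reps), function(i) {
    r <- walk_branch(sp, st, 3, 2, warn = FALSE)
    if (r$dead) 0 else exp(r$dlw)
  }, numeric(1))
  expect_within_3se(mean(w), exp(crbd_log_branch_factor(p, 3, 2)),
                    sd(w) / sqrt(reps))
})

test_that("observed node factors score the speciation intensity", {
  sp <- model_spec("CRBD", fixed = list(lambda = 0.4, mu = 0.1))
  st <- init_particle_state(sp, 5)
  nf <- observed_node_factor(sp, st, 2)
  expect_equal(nf$dlw, log(0.4))
  spt <- model_spec("TDBD", fixed = list(lambda = 0.2, z = -0.1, eps = 0.5))
  stt <- init_particle_state(spt, 10)
  nft <- observed_node_factor(spt, stt, 0)
  expect_equal(nft$dlw, log(0.2 * exp(-1)), tolerance = 1e-12)
  # delayed: the event update bumps the shape parameter
  spd <- model_spec("CRBD")
  std <- init_particle_state(spd, 5)
  nfd <- observed_node_factor(spd, std, 2)
  expect_equal(nfd$state$shared$lam$k, 2)
  expect_equal(nfd$dlw, log(1 * 1 / 1))
})

test_that("ClaDS children with no trend and no noise inherit the parent rate", {
  sp <- model_spec("ClaDS2", fixed = list(lambda = 0.4, log_alpha = 0,
                                          sigma2 = 0, mu = 0.2))
  st <- init_particle_state(sp, 5)
  nf <- observed_node_factor(sp, st, 2)
  expect_equal(nf$children[[1]]$m, 1)
  expect_equal(nf$children[[2]]$m, 1)
  expect_equal(nf$dlw, log(0.4))
})

test_that("ClaDS2 keeps turnover constant on every lineage", {
  # the same per-lineage multiplier scales both rates, so turnover
  # mu_i / lambda_i = mu0 / lambda0 whatever steps are drawn; check the
  # observable consequence: with alpha = 1, sigma = 0 the stem extinction
  # fraction equals the CRBD value at mu = eps * lambda (see simulate tests),
  # and the daughters inherit one common multiplier
  sp <- model_spec("ClaDS2", fixed = list(lambda = 0.5, log_alpha = -0.1,
                                          sigma2 = 0.05, mu = 0.2))
  st <- init_particle_state(sp, 5)
  set.seed(8)
  nf <- observed_node_factor(sp, st, 3)
  m1 <- nf$children[[1]]$m
  expect_gt(m1, 0)
  # the daughter's speciation and extinction rates share the multiplier:
  # lambda_i = lambda0 m1, mu_i = mu0 m1, hence mu_i/lambda_i = 0.4
  expect_equal((0.2 * m1) / (0.5 * m1), 0.4)
})

test_that("tip factor is log rho and sums over tips", {
  expect_equal(tip_factor(model_spec("CRB", rho = 1)), 0)
  expect_equal(tip_factor(model_spec("CRBD", rho = 0.5)), log(0.5))
  expect_equal(5 * tip_factor(model_spec("CRBD", rho = 0.8)), 5 * log(0.8))
})

test_that("orientation correction is (n-1) log 2", {
  expect_equal(orientation_correction(read_newick("(A:1,B:1);")), log(2))
  tr <- tree5()
  expect_equal(orientation_correction(tr), 4 * log(2))
})

test_that("survivorship correction: closed form and Monte Carlo agree", {
  sp1 <- model_spec("CRB", fixed = list(lambda = 0.4))
  expect_equal(survivorship_correction(sp1, 5), 0)
  sp2 <- model_spec("CRBD", fixed = list(lambda = 1, mu = 0.5))
  cf <- survivorship_correction(sp2, 10)
  expect_equal(cf, -2 * log(0.501689), tolerance = 1e-4)
  set.seed(10)
  mc <- survivorship_correction(sp2, 10, n_mc = 6000, force_mc = TRUE)
  # delta method SE on -2 log p
  p <- exp(-cf / 2)
  se <- 2 * sqrt((1 - p) / p / 6000)
  expect_within_3se(mc, cf, se)
  expect_error(survivorship_correction(sp2, 10, n_mc = 0), "n_mc")
})

test_that("eager and delayed modes give the same mean weight, delayed less spread", {
  tr <- tree3()
  runs <- 60
  set.seed(11)
  le <- rep_logz("smc", model_spec("CRBD", rho = 0.75, delayed = FALSE), tr, 150, runs, 0)
  ld <- rep_logz("smc", model_spec("CRBD", rho = 0.75, delayed = TRUE), tr, 150, runs, 500)
  se <- sqrt(var(exp(le)) / runs + var(exp(ld)) / runs)
  expect_within_3se(mean(exp(le)), mean(exp(ld)), se)
  expect_lt(var(ld), var(le))
})
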
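# The provenance chain for the analytic oracles: the extinction probability
# is validated against a direct simulation of the birth-death recursion, the
# per-branch factor against its ODE, and the likelihoods against small
# hand-computable cases and each other.

test_that("extinction probability: boundary values and known case", {
  expect_equal(extinction_prob_crbd(crbd_params(0.7, 0), 5), 0)
  p <- crbd_params(1, 0.5)
  expect_equal(extinction_prob_crbd(p, 0), 0)
  expect_equal(extinction_prob_crbd(p, 10), 0.498310, tolerance = 1e-5)
  # 1 - E = 0.5 / (1 - 0.5 exp(-5))
  expect_equal(1 - extinction_prob_crbd(p, 10), 0.5 / (1 - 0.5 * exp(-5)),
               tolerance = 1e-12)
  prho <- crbd_params(1, 0.5, rho = 0.6)
  expect_equal(extinction_prob_crbd(prho, 0), 0.4)
  # lambda == mu limit agrees with nearby lambda
  expect_equal(extinction_prob_crbd(crbd_params(0.5, 0.5), 4),
               extinction_prob_crbd(crbd_params(0.5 + 1e-9, 0.5), 4),
               tolerance = 1e-6)
})

test_that("extinction probability is monotone with limit 1 - mu/lambda", {
  p <- crbd_params(1, 0.4)
  t <- seq(0, 50, by = 0.5)
  E <- extinction_prob_crbd(p, t)
  expect_true(all(diff(E) >= -1e-12))
  expect_equal(1 - E[length(E)], 1 - 0.4, tolerance = 1e-6)
  E2 <- extinction_prob_crbd(crbd_params(1, 0.6), t)
  expect_true(all(E2 >= E - 1e-12))
})

test_that("extinction probability matches the simulation oracle", {
  E <- extinction_prob_crbd(crbd_params(1, 0.5), 10)
  reps <- 2e5
  Emc <- crbd_extinction_mc(1, 0.5, 10, reps = reps, seed = 99)
  expect_within_3se(Emc, E, sqrt(E * (1 - E) / reps))
  # with partial sampling
  E6 <- extinction_prob_crbd(crbd_params(0.8, 0.3, rho = 0.6), 6)
  Emc6 <- crbd_extinction_mc(0.8, 0.3, 6, rho = 0.6, reps = reps, seed = 100)
  expect_within_3se(Emc6, E6, sqrt(E6 * (1 - E6) / reps))
})

test_that("branch factor solves its ODE", {
  p <- crbd_params(0.9, 0.6, rho = 0.8)
  q_ode <- function(s) {
    f <- function(t, y, ...) {
      E <- extinction_prob_crbd(p, t)
      list(-(p$lambda + p$mu - 2 * p$lambda * E) * y)
    }
    unname(deSolve::lsoda(c(q = 1), c(0, s), f, rtol = 1e-11, atol = 1e-11)[2, "q"])
  }
  for (s in c(0.5, 2, 7)) {
    expect_equal(crbd_log_branch_factor(p, s, 0), log(q_ode(s)), tolerance = 1e-7)
  }
  # multiplicativity along a branch
  expect_equal(crbd_log_branch_factor(p, 7, 2) + crbd_log_branch_factor(p, 2, 0),
               crbd_log_branch_factor(p, 7, 0), tolerance = 1e-12)
})

test_that("Yule likelihood equals the brute-force exponential product", {
  tr <- tree3()
  lam <- 0.3
  # oriented Yule density of ((A:1,B:1):1,C:2): each branch contributes
  # exp(-lam * len) for no speciation, each non-root node the rate lam;
  # plus the (n-1) log 2 orientation constant
  by_hand <- -lam * 5 + log(lam) + 2 * log(2)
  expect_equal(crbd_loglik(tr, crbd_params(lam, 0)), by_hand, tolerance = 1e-12)
  expect_equal(crbd_loglik(tr, crbd_params(0, 0)), -Inf)
})

test_that("sampled-tip counts match the geometric law of the reconstructed process", {
  # P(k extant | survival, t) = (1 - xi) xi^(k-1),
  # xi = lambda (1 - exp(-rt)) / (lambda - mu exp(-rt)) -- classic result,
  # used as an independent check of the forward simulator
  lam <- 0.5; mu <- 0.2; t0 <- 5
  r <- lam - mu
  xi <- lam * (1 - exp(-r * t0)) / (lam - mu * exp(-r * t0))
  sp <- model_spec("CRBD", fixed = list(lambda = lam, mu = mu))
  st <- simulate_stem(sp, t0, reps = 4000, seed = 21)
  surv <- st$n_extant[st$n_extant > 0]
  for (k in 1:3) {
    pk <- (1 - xi) * xi^(k - 1)
    ph <- mean(surv == k)
    expect_within_3se(ph, pk, sqrt(pk * (1 - pk) / length(surv)))
  }
})

test_that("time-dependent likelihood collapses to the constant-rate one", {
  tr <- tree5()
  expect_equal(tdbd_loglik(tr, 0.2, 0, 0.5), crbd_loglik(tr, crbd_params(0.2, 0.1)),
               tolerance = 1e-6)
  expect_equal(tdbd_loglik(tr, 0.2, 0, 0), crbd_loglik(tr, crbd_params(0.2, 0)),
               tolerance = 1e-6)
  # constant-mu variant at z = 0 is the same thing
  expect_equal(tdbd_loglik(tr, 0.2, 0, mu_const = 0.1),
               crbd_loglik(tr, crbd_params(0.2, 0.1)), tolerance = 1e-6)
})

test_that("halving the integrator tolerance moves the result by < 1e-6", {
  tr <- tree5()
  a <- tdbd_loglik(tr, 0.3, -0.05, 0.5, tol = 1e-10)
  b <- tdbd_loglik(tr, 0.3, -0.05, 0.5, tol = 5e-11)
  expect_lt(abs(a - b), 1e-6)
})

test_that("survivorship conditioning divides by the crown survival probability", {
  tr <- tree5()
  p <- crbd_params(0.2, 0.1)
  E0 <- extinction_prob_crbd(p, tr$age[tr$root])
  expect_equal(crbd_loglik(tr, p, survivorship = TRUE),
               crbd_loglik(tr, p) - 2 * log1p(-E0), tolerance = 1e-12)
})
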
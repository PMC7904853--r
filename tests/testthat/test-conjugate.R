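# Oracles: brute-force quadrature over the gamma prior, direct arithmetic,
# and distributional identities.

test_that("gamma survival update matches direct integration", {
  b <- gamma_belief(1, 1)
  r <- gamma_observe_survival(b, 1, 0)
  expect_equal(r$belief, b)
  expect_equal(r$log_marginal, 0)
  r1 <- gamma_observe_survival(b, 1, 1)
  expect_equal(r1$belief$beta, 2)
  expect_equal(r1$log_marginal, log(1 / 2))
  # quadrature: int exp(-c T lambda) dGamma(lambda; k, beta)
  for (pars in list(c(1.5, 2, 0.7, 3), c(3, 0.5, 2, 1.2))) {
    k <- pars[1]; beta <- pars[2]; cc <- pars[3]; T <- pars[4]
    num <- integrate(function(l) exp(-cc * T * l) * dgamma(l, k, rate = beta),
                     0, Inf, rel.tol = 1e-10)$value
    r <- gamma_observe_survival(gamma_belief(k, beta), cc, T)
    expect_equal(r$log_marginal, log(num), tolerance = 1e-8)
  }
})

test_that("survival exposure is additive", {
  b <- gamma_belief(2.3, 1.7)
  r12 <- gamma_observe_survival(b, 0.8, 1.1)
  r12b <- gamma_observe_survival(r12$belief, 0.8, 2.2)
  once <- gamma_observe_survival(b, 0.8, 3.3)
  expect_equal(r12$log_marginal + r12b$log_marginal, once$log_marginal)
  expect_equal(r12b$belief, once$belief)
})

test_that("gamma event update gives the marginal intensity", {
  r <- gamma_observe_event(gamma_belief(1, 1), 1)
  expect_equal(r$belief$k, 2)
  expect_equal(r$log_marginal, 0)
  r2 <- gamma_observe_event(gamma_belief(2, 4), 0.5)
  expect_equal(r2$belief$k, 3)
  expect_equal(r2$log_marginal, log(0.25))
  expect_error(gamma_observe_event(gamma_belief(1, 1), 0), "positive")
})

test_that("survival then event reproduces the Lomax first-event density", {
  k <- 2; beta <- 4; cc <- 0.5; T <- 1.3
  s <- gamma_observe_survival(gamma_belief(k, beta), cc, T)
  e <- gamma_observe_event(s$belief, cc)
  # marginal density of first event at exactly T: c k beta^k / (beta + c T)^(k+1)
  expect_equal(s$log_marginal + e$log_marginal,
               log(cc * k * beta^k / (beta + cc * T)^(k + 1)))
  # numeric-integration oracle for the same density
  num <- integrate(function(l) cc * l * exp(-cc * T * l) * dgamma(l, k, rate = beta),
                   0, Inf, rel.tol = 1e-10)$value
  expect_equal(s$log_marginal + e$log_marginal, log(num), tolerance = 1e-8)
})

test_that("random survival/event chains match quadrature to 1e-6", {
  set.seed(31)
  for (rep in 1:10) {
    k0 <- runif(1, 0.5, 3); b0 <- runif(1, 0.5, 3)
    n_ops <- sample(3:7, 1)
    ops <- sample(c("surv", "event"), n_ops, replace = TRUE)
    cs <- runif(n_ops, 0.2, 2)
    Ts <- runif(n_ops, 0.1, 2)
    bel <- gamma_belief(k0, b0)
    total <- 0
    for (i in seq_len(n_ops)) {
      r <- if (ops[i] == "surv") gamma_observe_survival(bel, cs[i], Ts[i])
           else gamma_observe_event(bel, cs[i])
      bel <- r$belief
      total <- total + r$log_marginal
    }
    lik <- function(l) {
      out <- rep(1, length(l))
      for (i in seq_len(n_ops)) {
        out <- out * if (ops[i] == "surv") exp(-cs[i] * Ts[i] * l) else cs[i] * l
      }
      out
    }
    num <- integrate(function(l) lik(l) * dgamma(l, k0, rate = b0), 0, Inf,
                     rel.tol = 1e-10)$value
    expect_equal(exp(total), num, tolerance = 1e-6)
  }
})

test_that("gamma_sample has the right mean and distribution", {
  set.seed(5)
  x <- gamma_sample(gamma_belief(2, 4), 1e5)
  expect_within_3se(mean(x), 0.5, sd(x) / sqrt(1e5))
  set.seed(6)
  y <- gamma_sample(gamma_belief(1, 1), 1e5)
  expect_gt(stats::ks.test(y, "pexp")$p.value, 1e-4)
  set.seed(9); a <- gamma_sample(gamma_belief(2, 3))
  set.seed(9); b <- gamma_sample(gamma_belief(2, 3))
  expect_identical(a, b)
})

test_that("NIG updates are exchangeable and predictive integrates to 1", {
  xs <- c(0.3, -0.8, 1.1, 0.05)
  run_chain <- function(order) {
    bel <- nig_belief(0, 1, 1, 0.2)
    tot <- 0
    for (x in xs[order]) {
      r <- nig_observe_normal(bel, x)
      bel <- r$belief
      tot <- tot + r$log_marginal
    }
    list(bel = bel, tot = tot)
  }
  a <- run_chain(1:4)
  b <- run_chain(c(3, 1, 4, 2))
  expect_equal(a$tot, b$tot, tolerance = 1e-12)
  expect_equal(a$bel, b$bel, tolerance = 1e-12)
  bel <- nig_belief(0.4, 2, 1.5, 0.3)
  dens <- function(x) {
    vapply(x, function(xi) exp(nig_observe_normal(bel, xi)$log_marginal), 1)
  }
  expect_equal(integrate(dens, -Inf, Inf, rel.tol = 1e-8)$value, 1,
               tolerance = 1e-6)
})

test_that("NIG predictive approaches the normal density in the tight limit", {
  mu0 <- 0.3; s0 <- 0.5
  bel <- nig_belief(m = mu0, nu = 1e8, a = 1e8, b = 1e8 * s0^2)
  x <- c(-0.5, 0.3, 1.4)
  for (xi in x) {
    expect_equal(nig_observe_normal(bel, xi)$log_marginal,
                 dnorm(xi, mu0, s0, log = TRUE), tolerance = 1e-4)
  }
})

test_that("posterior mixtures behave like weighted sums of densities", {
  b1 <- gamma_belief(2, 4)
  one <- posterior_mixture(list(b1), 1)
  two <- posterior_mixture(list(b1, b1), c(0.5, 0.5), grid = one$grid)
  expect_equal(one$density, two$density)
  b2 <- gamma_belief(5, 2)
  mx <- posterior_mixture(list(b1, b2), c(0.3, 0.7))
  expect_equal(mx$mean, 0.3 * 0.5 + 0.7 * 2.5)
  # quantiles invert the mixture CDF
  med <- mx$quantiles[["q0.5"]]
  cdf <- 0.3 * pgamma(med, 2, 4) + 0.7 * pgamma(med, 5, 2)
  expect_equal(cdf, 0.5, tolerance = 1e-6)
  expect_error(posterior_mixture(list(), numeric(0)), "empty")
})
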
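# Conjugate belief types for delayed sampling.
#
# A particle can carry a distribution over a rate parameter instead of a
# sampled value. For a positive rate with a gamma prior, exposure to a
# Poisson process of intensity c*rate over a duration T and occurrences of
# point events are both conjugate updates, so the marginal probability of the
# particle's trajectory can be accumulated without ever realizing the rate
# (gamma-Poisson marginalization). The ClaDS inheritance steps use a
# normal-inverse-gamma belief over (log alpha, sigma^2), with Student-t
# predictive marginals.

#' Gamma belief over a positive rate
#'
#' Parameterized by shape `k` and **rate** `beta` (mean `k/beta`), so that
#' exposure updates are additive in `beta`.
#'
#' @param shape shape parameter k > 0.
#' @param rate rate parameter beta > 0.
#' @return Object of class `gamma_belief`.
#' @export
gamma_belief <- function(shape = 1, rate = 1) {
  if (!is.finite(shape) || !is.finite(rate) || shape <= 0 || rate <= 0) {
    stop_domain("gamma belief requires finite positive shape and rate")
  }
  structure(list(k = shape, beta = rate), class = "gamma_belief")
}

#' Observe survival (zero events) of a marginalized Poisson process
#'
#' The rate is `c * lambda` with `lambda ~ Gamma(k, beta)` marginalized out.
#' Observing zero events over an exposure `T` updates `beta <- beta + c*T`
#' and contributes the log-marginal `k * (log beta - log(beta + c*T))`.
#'
#' @param belief a `gamma_belief`.
#' @param multiplier nonnegative intensity multiplier c.
#' @param exposure nonnegative duration T.
#' @return `list(belief =, log_marginal =)`.
#' @export
gamma_observe_survival <- function(belief, multiplier, exposure) {
  if (multiplier < 0 || exposure < 0) stop_domain("multiplier and exposure must be nonnegative")
  ct <- multiplier * exposure
  list(belief = gamma_belief(belief$k, belief$beta + ct),
       log_marginal = belief$k * (log(belief$beta) - log(belief$beta + ct)))
}

#' Observe one point event of a marginalized Poisson process
#'
#' Updates `k <- k + 1` and contributes the log marginal intensity
#' `log(c * k / beta)`.
#'
#' @param belief a `gamma_belief`.
#' @param multiplier positive intensity multiplier c.
#' @return `list(belief =, log_marginal =)`.
#' @export
gamma_observe_event <- function(belief, multiplier) {
  if (multiplier <= 0) stop_domain("event multiplier must be positive")
  list(belief = gamma_belief(belief$k + 1, belief$beta),
       log_marginal = log(multiplier) + log(belief$k) - log(belief$beta))
}

#' Draw a realization from a gamma belief
#'
#' @param belief a `gamma_belief`.
#' @param n number of draws.
#' @return Positive draws from Gamma(k, rate = beta).
#' @export
gamma_sample <- function(belief, n = 1) {
  stats::rgamma(n, shape = belief$k, rate = belief$beta)
}

# First-event waiting time of the marginalized process (Lomax), by inversion
# of the survival function (beta/(beta + c t))^k. Returns the waiting time;
# the caller commits the matching belief update (exposure, and the event
# increment if the event falls inside the horizon).
#' @noRd
gamma_wait <- function(belief, multiplier) {
  if (multiplier <= 0) return(Inf)
  belief$beta * (runif(1)^(-1 / belief$k) - 1) / multiplier
}

#' Normal-inverse-gamma belief over (mean, variance)
#'
#' `variance ~ InvGamma(a, b)` and `mean | variance ~ N(m, variance/nu)`.
#' Used for the ClaDS step distribution, where the mean is `log alpha` and
#' the variance is `sigma^2`.
#'
#' @param m location.
#' @param nu precision scale (> 0).
#' @param a shape (> 0).
#' @param b scale (> 0).
#' @return Object of class `nig_belief`.
#' @export
nig_belief <- function(m = 0, nu = 1, a = 1, b = 0.2) {
  if (!all(is.finite(c(m, nu, a, b))) || nu <= 0 || a <= 0 || b <= 0) {
    stop_domain("nig belief requires finite hyperparameters with nu, a, b > 0")
  }
  structure(list(m = m, nu = nu, a = a, b = b), class = "nig_belief")
}

# Student-t predictive parameters for the next observation.
#' @noRd
nig_predictive <- function(belief) {
  df <- 2 * belief$a
  scale <- sqrt(belief$b * (belief$nu + 1) / (belief$a * belief$nu))
  list(df = df, loc = belief$m, scale = scale)
}

#' Observe a normal draw under a normal-inverse-gamma belief
#'
#' Standard conjugate update; the log-marginal is the Student-t predictive
#' density of `x`.
#'
#' @param belief a `nig_belief`.
#' @param x observed real value.
#' @return `list(belief =, log_marginal =)`.
#' @export
nig_observe_normal <- function(belief, x) {
  if (!is.finite(x)) stop_domain("observation must be finite")
  pred <- nig_predictive(belief)
  lm <- stats::dt((x - pred$loc) / pred$scale, df = pred$df, log = TRUE) - log(pred$scale)
  nu1 <- belief$nu + 1
  upd <- nig_belief(
    m = (belief$nu * belief$m + x) / nu1,
    nu = nu1,
    a = belief$a + 0.5,
    b = belief$b + belief$nu * (x - belief$m)^2 / (2 * nu1))
  list(belief = upd, log_marginal = lm)
}

# Draw from the Student-t predictive of a NIG belief (a prior sample of the
# next step; callers commit the nig_observe_normal update).
#' @noRd
nig_predictive_sample <- function(belief) {
  pred <- nig_predictive(belief)
  pred$loc + pred$scale * stats::rt(1, df = pred$df)
}

# ---------------------------------------------------------------------------
# Mixture summaries of weighted belief ensembles.

#' @noRd
belief_density <- function(component, x) {
  if (inherits(component, "gamma_belief")) {
    stats::dgamma(x, shape = component$k, rate = component$beta)
  } else if (inherits(component, "nig_belief")) {
    # marginal of the location (log alpha): t with scale sqrt(b/(a nu))
    s <- sqrt(component$b / (component$a * component$nu))
    stats::dt((x - component$m) / s, df = 2 * component$a) / s
  } else if (inherits(component, "invgamma_belief")) {
    a <- component$a; b <- component$b
    ifelse(x > 0, exp(a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x), 0)
  } else {
    stop_domain("unsupported mixture component")
  }
}

#' @noRd
belief_cdf <- function(component, x) {
  if (inherits(component, "gamma_belief")) {
    stats::pgamma(x, shape = component$k, rate = component$beta)
  } else if (inherits(component, "nig_belief")) {
    s <- sqrt(component$b / (component$a * component$nu))
    stats::pt((x - component$m) / s, df = 2 * component$a)
  } else if (inherits(component, "invgamma_belief")) {
    ifelse(x > 0, 1 - stats::pgamma(1 / x, shape = component$a, rate = component$b), 0)
  } else {
    stop_domain("unsupported mixture component")
  }
}

#' @noRd
belief_mean <- function(component) {
  if (inherits(component, "gamma_belief")) component$k / component$beta
  else if (inherits(component, "nig_belief")) component$m
  else if (inherits(component, "invgamma_belief")) {
    if (component$a > 1) component$b / (component$a - 1) else Inf
  } else stop_domain("unsupported mixture component")
}

#' Inverse-gamma marginal over the variance of a NIG belief
#' @param belief a `nig_belief`.
#' @return Object of class `invgamma_belief` with fields `a`, `b`.
#' @export
nig_variance_marginal <- function(belief) {
  structure(list(a = belief$a, b = belief$b), class = "invgamma_belief")
}

#' Weighted mixture summary of a belief ensemble
#'
#' Delayed sampling leaves each particle holding a conjugate posterior
#' belief; the SMC posterior of the parameter is then the weighted mixture of
#' those beliefs. Returns the mixture density on a grid and quantiles by
#' numerical inversion of the mixture CDF.
#'
#' @param components list of belief objects (`gamma_belief`, `nig_belief`
#'   for the location marginal, or `invgamma_belief`).
#' @param weights normalized particle weights.
#' @param grid evaluation grid (default: spanned automatically).
#' @param probs quantile probabilities.
#' @return list with `grid`, `density`, `quantiles`, `mean`.
#' @export
posterior_mixture <- function(components, weights,
                              grid = NULL, probs = c(0.025, 0.5, 0.975)) {
  if (!length(components)) stop_domain("empty ensemble")
  if (length(weights) != length(components)) stop_domain("weights/components mismatch")
  weights <- weights / sum(weights)
  if (is.null(grid)) {
    qs <- unlist(lapply(components, function(cc) {
      mixture_component_range(cc)
    }))
    grid <- seq(min(qs), max(qs), length.out = 512)
  }
  dens <- Reduce(`+`, Map(function(cc, w) w * belief_density(cc, grid),
                          components, weights))
  cdf <- function(x) {
    sum(unlist(Map(function(cc, w) w * belief_cdf(cc, x), components, weights)))
  }
  lo <- min(grid); hi <- max(grid)
  quantiles <- vapply(probs, function(p) {
    f <- function(x) cdf(x) - p
    if (f(lo) >= 0) return(lo)
    if (f(hi) <= 0) return(hi)
    stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  }, numeric(1))
  names(quantiles) <- paste0("q", probs)
  mixmean <- sum(weights * vapply(components, belief_mean, numeric(1)))
  list(grid = grid, density = dens, quantiles = quantiles, mean = mixmean)
}

#' @noRd
mixture_component_range <- function(component) {
  if (inherits(component, "gamma_belief")) {
    stats::qgamma(c(1e-5, 1 - 1e-5), shape = component$k, rate = component$beta)
  } else if (inherits(component, "nig_belief")) {
    s <- sqrt(component$b / (component$a * component$nu))
    component$m + s * stats::qt(c(1e-5, 1 - 1e-5), df = 2 * component$a)
  } else if (inherits(component, "invgamma_belief")) {
    1 / stats::qgamma(c(1 - 1e-5, 1e-4), shape = component$a, rate = component$b)
  } else stop_domain("unsupported mixture component")
}
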
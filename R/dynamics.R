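# Rate dynamics: exponential time dependence and ClaDS inheritance steps.

#' Time-dependent speciation rate
#'
#' `lambda(t) = lambda0 * exp(z * (t_ref - t))` with ages measured backward
#' from the present: `t_ref` is the reference (initial) age, `t <= t_ref` the
#' age at which the rate is evaluated. `z < 0` gives rates that decay toward
#' the present (niche filling); `z = 0` is the constant-rate limit.
#'
#' @param lambda0 initial rate at `t_ref`.
#' @param z exponential dependence parameter.
#' @param t_ref reference age.
#' @param t evaluation age (`<= t_ref`), vectorized.
#' @return Rate(s).
#' @export
lambda_t <- function(lambda0, z, t_ref, t) {
  if (any(t > t_ref + 1e-12)) stop_domain("lambda_t requires t <= t_ref")
  lambda0 * exp(z * (t_ref - t))
}

# Integrated intensity of lambda(t) from age a down to age b (a >= b).
#' @noRd
tdbd_intensity <- function(lambda0, z, t_ref, a, b) {
  if (abs(z) < 1e-12) return(lambda0 * (a - b))
  lambda0 / z * (exp(z * (t_ref - b)) - exp(z * (t_ref - a)))
}

# Exact waiting time (in age units, measured downward from age `a`) until the
# next event of an inhomogeneous Poisson process with rate lambda(t), by
# inversion of the integrated intensity; Inf if the process never fires
# (possible when z < 0 and the remaining mass is below the exponential draw).
#' @noRd
tdbd_wait <- function(lambda0, z, t_ref, a) {
  if (lambda0 <= 0) return(Inf)
  if (z * (t_ref - a) > 700) return(0) # rate overflows double: immediate event
  x <- rexp(1)
  if (abs(z) < 1e-12) return(x / (lambda0 * exp(z * (t_ref - a))))
  arg <- exp(z * (t_ref - a)) + z * x / lambda0
  if (arg <= 0) return(Inf)
  a - (t_ref - log(arg) / z)
}

#' Draw a daughter speciation rate under the ClaDS inheritance model
#'
#' `log lambda_i ~ Normal(log(alpha * lambda_a), sigma^2)`: each daughter's
#' initial rate is a lognormal perturbation of its parent's ending rate, with
#' long-term trend `alpha = exp(log_alpha)` and noise `sigma2`. `sigma2 = 0`
#' gives the deterministic step `lambda_i = alpha * lambda_a`.
#'
#' @param lambda_a parent rate (> 0).
#' @param log_alpha log of the trend parameter.
#' @param sigma2 step variance (>= 0).
#' @return A positive daughter rate.
#' @export
clads_child_rate <- function(lambda_a, log_alpha, sigma2) {
  if (lambda_a <= 0) stop_domain("parent rate must be positive")
  if (sigma2 < 0) stop_domain("sigma2 must be nonnegative")
  exp(log(lambda_a) + log_alpha + sqrt(sigma2) * stats::rnorm(1))
}
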
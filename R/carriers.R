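# Rate carriers: a rate parameter inside a particle is either a realized
# numeric value (eager / fixed) or a gamma belief (delayed). The helpers
# below give walk code one interface for the three things a carrier must
# support: an observed non-event over an exposure (weighted), an observed
# point event (weighted), and sampling the waiting time to the next event of
# the (marginalized) Poisson process it drives (unweighted; the belief update
# is committed once the competing-event winner is known).
#
# These run in the innermost simulation loop; belief updates mutate the
# fields directly instead of going through the validating constructor.

#' @noRd
carrier_is_belief <- function(car) inherits(car, "gamma_belief")

# Observed zero events over exposure T at intensity c * rate.
# Returns list(car, lm).
#' @noRd
carrier_surv <- function(car, c_mult, T) {
  if (T <= 0 || c_mult <= 0) return(list(car = car, lm = 0))
  if (is.list(car)) {
    ct <- c_mult * T
    lm <- car$k * (log(car$beta) - log(car$beta + ct))
    car$beta <- car$beta + ct
    list(car = car, lm = lm)
  } else {
    list(car = car, lm = -c_mult * car * T)
  }
}

# Observed point event at intensity c * rate. Returns list(car, lm).
#' @noRd
carrier_event <- function(car, c_mult) {
  if (is.list(car)) {
    lm <- log(c_mult) + log(car$k) - log(car$beta)
    car$k <- car$k + 1
    list(car = car, lm = lm)
  } else {
    if (car <= 0 || c_mult <= 0) return(list(car = car, lm = -Inf))
    list(car = car, lm = log(c_mult * car))
  }
}

# Candidate waiting time of the next event (prior sample, uncommitted).
#' @noRd
carrier_wait <- function(car, c_mult) {
  if (c_mult <= 0) return(Inf)
  if (is.list(car)) {
    car$beta * (runif(1)^(-1 / car$k) - 1) / c_mult
  } else {
    if (car <= 0) Inf else rexp(1, c_mult * car)
  }
}

# Commit the sampled outcome over a horizon tau: either the event fired at
# tau (event = TRUE) or no event occurred during tau. Prior samples carry no
# weight; beliefs absorb the exposure (and the event count).
#' @noRd
carrier_commit <- function(car, c_mult, tau, event) {
  if (!is.list(car) || c_mult <= 0) return(car)
  ct <- c_mult * tau
  # Inf * 0 (an overflowing multiplier with a zero waiting time) carries no
  # exposure; leave beta unchanged rather than poisoning it with NaN
  if (is.finite(ct)) car$beta <- car$beta + ct
  if (event) car$k <- car$k + 1
  car
}

# Realize a carrier (draw a value from the belief); numerics pass through.
#' @noRd
carrier_realize <- function(car) {
  if (is.list(car)) gamma_sample(car) else car
}

# Posterior mean of the rate under the carrier.
#' @noRd
carrier_mean <- function(car) {
  if (is.list(car)) car$k / car$beta else car
}

# Build a carrier for a parameter: fixed value if provided, else the gamma
# prior as a belief (delayed) or a realized draw (eager).
#' @noRd
make_rate_carrier <- function(spec, name) {
  if (!is.null(spec$fixed[[name]])) return(spec$fixed[[name]])
  pr <- spec$priors[[name]]
  bel <- gamma_belief(pr$shape, pr$rate)
  if (spec$delayed) bel else gamma_sample(bel)
}
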
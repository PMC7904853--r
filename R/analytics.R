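# Closed-form and quadrature oracles for the constant-rate and
# time-dependent birth-death processes.
#
# Notation: lambda = speciation rate, mu = extinction rate, rho = probability
# that an extant lineage is sampled at the present, t = age before present.
# E(t) is the probability that a single lineage alive at age t leaves no
# sampled descendant. The per-branch factor q(s, e) is the probability that a
# lineage at age s descends to a single lineage at age e with every side
# branch leaving no sampled descendant; it satisfies
#   dq/dt = -(lambda + mu - 2 lambda E(t)) q
# (the factor 2 because either daughter of a hidden speciation may be the
# unsampled one).

#' Parameters of the constant-rate birth-death process
#'
#' @param lambda speciation rate (>= 0).
#' @param mu extinction rate (>= 0).
#' @param rho sampling probability in (0, 1].
#' @return Object of class `crbd_params`.
#' @export
crbd_params <- function(lambda, mu = 0, rho = 1) {
  if (lambda < 0 || mu < 0) stop_domain("rates must be nonnegative")
  if (rho <= 0 || rho > 1) stop_domain("rho must be in (0, 1]")
  structure(list(lambda = lambda, mu = mu, rho = rho), class = "crbd_params")
}

#' Extinction probability of the rho-sampled constant-rate birth-death process
#'
#' Probability `E(t)` that a single lineage alive at age `t` leaves no sampled
#' descendant at the present. For `lambda != mu`,
#' `E(t) = 1 - rho (lambda - mu) / (rho lambda + (lambda (1 - rho) - mu) e^{-(lambda - mu) t})`;
#' the `lambda == mu` limit is `1 - rho / (1 + rho lambda t)`.
#'
#' @param p a `crbd_params`.
#' @param t age (>= 0), may be a vector.
#' @return Probability (vectorized over `t`).
#' @export
#' @examples
#' extinction_prob_crbd(crbd_params(1, 0.5), 10)  # ~0.49831
extinction_prob_crbd <- function(p, t) {
  if (any(t < 0)) stop_domain("age must be nonnegative")
  if (abs(p$lambda - p$mu) < 1e-12) {
    if (p$lambda == 0) return(rep(1 - p$rho, length(t)))
    return(1 - p$rho / (1 + p$rho * p$lambda * t))
  }
  r <- p$lambda - p$mu
  D <- p$rho * p$lambda + (p$lambda * (1 - p$rho) - p$mu) * exp(-r * t)
  1 - p$rho * r / D
}

#' Log per-branch survival-conditioned factor of the CRBD process
#'
#' `log q(s, e)` for a branch running from parent age `s` down to child age
#' `e` (`s >= e`): the probability that the lineage persists with no
#' extinction and no hidden side branch leaving sampled descendants.
#'
#' @param p a `crbd_params`.
#' @param s parent age.
#' @param e child age (`<= s`).
#' @return Log factor (vectorized).
#' @export
crbd_log_branch_factor <- function(p, s, e) {
  if (any(e > s + 1e-12)) stop_domain("branch requires child age <= parent age")
  if (abs(p$lambda - p$mu) < 1e-12) {
    if (p$lambda == 0) return(rep(0, length(s)))
    return(2 * (log1p(p$rho * p$lambda * e) - log1p(p$rho * p$lambda * s)))
  }
  r <- p$lambda - p$mu
  # D keeps the sign of (lambda - mu) for all t; it enters squared, so use |D|
  D <- function(t) p$rho * p$lambda + (p$lambda * (1 - p$rho) - p$mu) * exp(-r * t)
  -r * (s - e) + 2 * (log(abs(D(e))) - log(abs(D(s))))
}

#' Log-likelihood of an observed tree under the CRBD model
#'
#' Reconstructed-process density of an ultrametric tree: per-branch
#' survival-conditioned factors, the speciation intensity at every non-root
#' internal node, and the sampling probability at every tip. The crown age is
#' treated as given (no factor at the root). With `orientation = TRUE`
#' (default) the `(n-1) log 2` orientation constant is included, matching the
#' convention of the SMC engines after their orientation correction. With
#' `survivorship = TRUE` the density is conditioned on both crown lineages
#' leaving sampled descendants.
#'
#' @param tree ultrametric `time_tree`.
#' @param p a `crbd_params`.
#' @param orientation include the `(n-1) log 2` constant.
#' @param survivorship condition on crown survival.
#' @return Log-likelihood.
#' @export
crbd_loglik <- function(tree, p, orientation = TRUE, survivorship = FALSE) {
  validate_time_tree(tree)
  if (!is_ultrametric_tree(tree)) stop_domain("crbd_loglik requires an ultrametric tree")
  n <- tree$n_tips
  nonroot <- which(!is.na(tree$parent))
  s <- tree$age[tree$parent[nonroot]]
  e <- tree$age[nonroot]
  ll <- sum(crbd_log_branch_factor(p, s, e))
  internal_nonroot <- nonroot[!tree$is_tip[nonroot]]
  n_spec <- length(internal_nonroot)
  if (n_spec > 0) {
    ll <- ll + if (p$lambda > 0) n_spec * log(p$lambda) else -Inf
  }
  ll <- ll + n * log(p$rho)
  if (orientation) ll <- ll + (n - 1) * log(2)
  if (survivorship) {
    E0 <- extinction_prob_crbd(p, tree$age[tree$root])
    ll <- ll - 2 * log1p(-E0)
  }
  ll
}

#' Log-likelihood of an observed tree under the time-dependent birth-death model
#'
#' Speciation rate `lambda(t) = lambda0 exp(z (t0 - t))` with `t0` the crown
#' age; extinction either proportional to it (`mu(t) = eps lambda(t)`,
#' constant turnover) or constant (`mu_const`). The extinction probability
#' and per-branch factors are obtained by numerically integrating their ODEs
#' (lsoda, absolute and relative tolerance `tol`); `z = 0` reproduces
#' [crbd_loglik()] to high accuracy.
#'
#' @param tree ultrametric `time_tree`.
#' @param lambda0 initial speciation rate at the crown age.
#' @param z exponential time-dependence parameter (z < 0: slowing rates).
#' @param eps turnover `mu/lambda` (ignored when `mu_const` is given).
#' @param rho sampling probability.
#' @param mu_const optional constant extinction rate (the BAMM-style variant).
#' @param orientation include the `(n-1) log 2` constant.
#' @param survivorship condition on crown survival.
#' @param tol integrator tolerance.
#' @return Log-likelihood.
#' @export
tdbd_loglik <- function(tree, lambda0, z, eps = 0, rho = 1, mu_const = NULL,
                        orientation = TRUE, survivorship = FALSE, tol = 1e-10) {
  validate_time_tree(tree)
  if (!is_ultrametric_tree(tree)) stop_domain("tdbd_loglik requires an ultrametric tree")
  if (lambda0 < 0 || eps < 0 || rho <= 0 || rho > 1) stop_domain("invalid parameters")
  t0 <- tree$age[tree$root]
  lam <- function(t) lambda0 * exp(z * (t0 - t))
  muf <- if (is.null(mu_const)) function(t) eps * lam(t) else function(t) rep(mu_const, length(t))
  ages <- sort(unique(c(0, tree$age)))
  deriv <- function(t, y, parms) {
    l <- lam(t); m <- muf(t)
    list(c(m - (l + m) * y[1] + l * y[1]^2,
           -(l + m - 2 * l * y[1])))
  }
  sol <- deSolve::lsoda(y = c(E = 1 - rho, lphi = 0), times = ages,
                        func = deriv, rtol = tol, atol = tol)
  if (any(is.na(sol))) stop("time-dependent birth-death integrator failed", call. = FALSE)
  Efun <- stats::approxfun(sol[, "time"], sol[, "E"], rule = 2)
  Lfun <- stats::approxfun(sol[, "time"], sol[, "lphi"], rule = 2)
  n <- tree$n_tips
  nonroot <- which(!is.na(tree$parent))
  s <- tree$age[tree$parent[nonroot]]
  e <- tree$age[nonroot]
  ll <- sum(Lfun(s) - Lfun(e))
  internal_nonroot <- nonroot[!tree$is_tip[nonroot]]
  if (length(internal_nonroot) > 0) {
    lt <- lam(tree$age[internal_nonroot])
    ll <- ll + if (all(lt > 0)) sum(log(lt)) else -Inf
  }
  ll <- ll + n * log(rho)
  if (orientation) ll <- ll + (n - 1) * log(2)
  if (survivorship) ll <- ll - 2 * log1p(-Efun(t0))
  ll
}
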
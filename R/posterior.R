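# Posterior summaries of SMC ensembles.
#
# Delayed sampling leaves conjugate beliefs inside the particles, so the
# posterior of a rate parameter is a weighted mixture of gamma densities,
# of Student-t densities (log alpha), or of inverse-gamma densities
# (sigma^2); realized parameters (z, eps, eager draws) are summarized by
# their weighted empirical distribution.

#' Extract the posterior representation of a parameter from an SMC result
#'
#' @param result an `smc_result`.
#' @param param one of `"lambda"`, `"mu"`, `"z"`, `"eps"`, `"log_alpha"`,
#'   `"sigma2"`, `"eta"` (availability depends on the model).
#' @return `list(type = "mixture", components =, weights =)` for delayed
#'   parameters, or `list(type = "values", values =, weights =)` for
#'   realized ones.
#' @export
posterior_param <- function(result, param) {
  w <- result$weights
  if (param == "eps" && result$model == "ClaDS2" && result$engine != "is") {
    # turnover is the ratio of the two delayed rates mu0 / lambda0
    return(list(type = "ratio",
                num = lapply(result$particles, `[[`, "mu"),
                den = lapply(result$particles, `[[`, "lam0"),
                weights = w))
  }
  if (result$engine == "is") {
    vals <- vapply(result$particles, function(d) {
      v <- d[[param]]
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
    if (all(is.na(vals))) stop_domain("parameter %s not present in this result", param)
    return(list(type = "values", values = vals, weights = w))
  }
  get1 <- function(sh) posterior_carrier(result$model, sh, param)
  cars <- lapply(result$particles, get1)
  if (is.list(cars[[1]])) {
    list(type = "mixture", components = cars, weights = w)
  } else {
    list(type = "values", values = unlist(cars), weights = w)
  }
}

#' @noRd
posterior_carrier <- function(model, sh, param) {
  pick <- switch(model,
    CRB = list(lambda = sh$lam, mu = NULL),
    CRBD = list(lambda = sh$lam, mu = sh$mu),
    TDB = list(lambda = sh$lambda0, z = sh$z),
    TDBD = list(lambda = sh$lambda0, z = sh$z, eps = sh$eps),
    ClaDS0 = clads_posterior(sh),
    ClaDS1 = clads_posterior(sh),
    ClaDS2 = clads_posterior(sh),
    LSBDS = list(lambda = sh$regimes[[1]]$lam, mu = sh$mu, eta = sh$eta),
    BAMM = list(lambda = sh$root_regime$lambda0, mu = sh$root_regime$mu,
                z = sh$root_regime$z, eta = sh$eta))
  v <- pick[[param]]
  if (is.null(v)) stop_domain("parameter %s not tracked for model %s", param, model)
  v
}

#' @noRd
clads_posterior <- function(sh) {
  out <- list(lambda = sh$lam0, mu = sh$mu)
  if (inherits(sh$step, "clads_fixed")) {
    out$log_alpha <- sh$step$log_alpha
    out$sigma2 <- sh$step$sigma2
  } else {
    out$log_alpha <- sh$step
    out$sigma2 <- nig_variance_marginal(sh$step)
  }
  out
}

#' Pool several independent SMC results into one posterior ensemble
#'
#' Particles of independent runs on the same tree are combined with weights
#' proportional to each run's marginal-likelihood estimate times its
#' normalized particle weights — the self-normalized combination that targets
#' the same posterior with lower variance than any single run. The pooled
#' `log_z` is the log mean of the runs' likelihood estimates.
#'
#' @param results list of `smc_result` objects for the same tree and model.
#' @return A pooled `smc_result`.
#' @export
pool_smc_results <- function(results) {
  if (!length(results)) stop_domain("no results to pool")
  sig <- results[[1]]$tree_signature
  for (r in results) {
    if (!isTRUE(all.equal(r$tree_signature, sig))) {
      stop_domain("results are not from the same tree")
    }
  }
  lz <- vapply(results, `[[`, numeric(1), "log_z")
  w_run <- exp(lz - max(lz))
  weights <- unlist(Map(function(r, wr) wr * r$weights / sum(r$weights),
                        results, w_run))
  out <- results[[1]]
  out$particles <- do.call(c, lapply(results, `[[`, "particles"))
  out$weights <- weights / sum(weights)
  out$log_z <- log_mean_exp(lz)
  out$n_particles <- sum(vapply(results, `[[`, numeric(1), "n_particles"))
  out
}

#' Posterior credible interval for a parameter
#'
#' Quantiles of the weighted mixture (by numerical inversion of the mixture
#' CDF) or of the weighted empirical distribution of realized draws.
#'
#' @param result an `smc_result`.
#' @param param parameter name (see [posterior_param()]).
#' @param probs quantile probabilities.
#' @return Named numeric vector of quantiles.
#' @export
posterior_interval <- function(result, param, probs = c(0.025, 0.975)) {
  po <- posterior_param(result, param)
  if (po$type == "mixture") {
    posterior_mixture(po$components, po$weights, probs = probs)$quantiles
  } else if (po$type == "ratio") {
    dr <- ratio_draws(po)
    setNames(unname(stats::quantile(dr, probs)), paste0("q", probs))
  } else {
    setNames(weighted_quantile(po$values, po$weights, probs),
             paste0("q", probs))
  }
}

# Monte Carlo draws from a weighted mixture of carrier ratios.
#' @noRd
ratio_draws <- function(po, n_draws = 20000) {
  idx <- sample.int(length(po$weights), n_draws, replace = TRUE, prob = po$weights)
  counts <- tabulate(idx, length(po$weights))
  draw1 <- function(car, n) {
    if (is.list(car)) rgamma(n, shape = car$k, rate = car$beta) else rep(car, n)
  }
  unlist(lapply(which(counts > 0), function(i) {
    draw1(po$num[[i]], counts[i]) / draw1(po$den[[i]], counts[i])
  }))
}

#' Posterior density table for a parameter
#'
#' Evaluates the posterior (mixture or weighted kernel-free histogram
#' summary) on a grid, suitable for TSV export and plotting.
#'
#' @inheritParams posterior_interval
#' @param grid optional evaluation grid.
#' @return data.frame with columns `value` and `density` (for mixtures) or
#'   `value` and `weight` (for realized draws).
#' @export
posterior_density <- function(result, param, grid = NULL) {
  po <- posterior_param(result, param)
  if (po$type == "mixture") {
    mx <- posterior_mixture(po$components, po$weights, grid = grid)
    data.frame(value = mx$grid, density = mx$density)
  } else if (po$type == "ratio") {
    dr <- ratio_draws(po)
    data.frame(value = dr, weight = 1 / length(dr))
  } else {
    data.frame(value = po$values, weight = po$weights / sum(po$weights))
  }
}
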
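# Internal numeric helpers shared across the package.

#' @noRd
log_sum_exp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

# Normalize log-weights to probabilities; all -Inf -> error handled by caller.
#' @noRd
norm_weights <- function(lw) {
  m <- max(lw)
  if (!is.finite(m)) return(rep(0, length(lw)))
  w <- exp(lw - m)
  w / sum(w)
}

#' @noRd
stop_domain <- function(...) stop(sprintf(...), call. = FALSE)

# Weighted empirical quantile (type-1 step interpolation on sorted values).
#' @noRd
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}
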
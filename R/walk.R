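# Generative model programs along the observed tree.
#
# A particle simulates the hidden part of the diversification process along
# each observed branch, conditioning on what is observed: the lineage itself
# does not go extinct (a weighted non-event), hidden speciations spawn side
# branches that must leave no sampled descendant (simulated; a log 2 factor
# per hidden speciation because either daughter may be the unsampled one),
# observed speciation events occur at the lineage's current rate (a weighted
# point event), and every observed tip is sampled (a log rho factor).
#
# A particle's state has two layers:
#   shared - parameters and beliefs shared across the whole particle
#            (rate carriers, the ClaDS step belief, the LSBDS regime table),
#   lin    - the per-lineage state attached to one frontier branch
#            (ClaDS rate multiplier, LSBDS regime id, BAMM regime).
# Rate carriers are either realized numerics (eager / fixed mode) or gamma
# beliefs (delayed sampling); see carriers.R.
#
# When the model guarantees mu = 0 and rho = 1 (CRB, TDB, ClaDS0), any
# hidden speciation would make the particle dead with certainty, so the walk
# conditions on zero hidden events analytically: it accumulates the
# no-event probability (-integral of lambda dt, or the gamma survival
# marginal when lambda is delayed) and draws nothing.

#' Initialize the per-particle state for a model
#'
#' Builds the shared parameter state (carriers, beliefs, regime table) and
#' the per-lineage state attached to the two crown lineages.
#'
#' @param spec a `model_spec`.
#' @param t0 crown age of the observed tree.
#' @return `list(shared =, lin =)`; `lin` is the state both crown lineages
#'   start from.
#' @export
init_particle_state <- function(spec, t0) {
  m <- spec$model
  if (m %in% c("CRB", "CRBD")) {
    shared <- list(lam = make_rate_carrier(spec, "lambda"),
                   mu = if (m == "CRBD") make_rate_carrier(spec, "mu") else 0)
    lin <- NULL
  } else if (m %in% c("TDB", "TDBD")) {
    shared <- list(lambda0 = realize_param(spec, "lambda"),
                   z = realize_param(spec, "z"),
                   eps = if (m == "TDBD") realize_param(spec, "eps") else 0,
                   t0 = t0)
    lin <- NULL
  } else if (m %in% c("ClaDS0", "ClaDS1", "ClaDS2")) {
    # ClaDS2 keeps turnover constant by scaling an independent mu0 belief
    # with the same per-lineage multiplier as lambda0
    shared <- list(lam0 = make_rate_carrier(spec, "lambda"),
                   step = make_step_carrier(spec),
                   mu = if (m %in% c("ClaDS1", "ClaDS2")) make_rate_carrier(spec, "mu") else NULL)
    lin <- list(m = 1)
  } else if (m == "LSBDS") {
    shared <- list(regimes = list(lsbds_regime(spec)),
                   mu = make_rate_carrier(spec, "mu"),
                   eta = make_rate_carrier(spec, "eta"))
    lin <- list(regime = 1L)
  } else if (m == "BAMM") {
    lin <- list(lambda0 = realize_param(spec, "lambda"),
                mu = realize_param(spec, "mu"),
                z = realize_param(spec, "z"),
                t_ref = t0)
    # keep the root regime in the shared state for posterior summaries
    shared <- list(eta = make_rate_carrier(spec, "eta"), t0 = t0,
                   root_regime = lin)
  } else stop_domain("unknown model")
  list(shared = shared, lin = lin)
}

# Realize a scalar parameter: fixed value, or a draw from its prior.
#' @noRd
realize_param <- function(spec, name) {
  if (!is.null(spec$fixed[[name]])) return(spec$fixed[[name]])
  if (name == "z") {
    pr <- spec$priors$z
    stats::rnorm(1, pr$mean, pr$sd)
  } else if (name == "eps") {
    pr <- spec$priors$eps
    stats::runif(1, pr$min, pr$max)
  } else {
    pr <- spec$priors[[name]]
    stats::rgamma(1, shape = pr$shape, rate = pr$rate)
  }
}

# ClaDS step carrier: NIG belief (delayed), realized (log alpha, sigma2)
# (eager), or fixed values.
#' @noRd
make_step_carrier <- function(spec) {
  fx <- spec$fixed
  if (!is.null(fx$log_alpha) || !is.null(fx$sigma2)) {
    if (is.null(fx$log_alpha) || is.null(fx$sigma2)) {
      stop_domain("ClaDS fixed mode needs both log_alpha and sigma2")
    }
    return(structure(list(log_alpha = fx$log_alpha, sigma2 = fx$sigma2),
                     class = "clads_fixed"))
  }
  pr <- spec$priors$clads
  bel <- nig_belief(pr$m, pr$nu, pr$a, pr$b)
  if (spec$delayed) return(bel)
  s2 <- 1 / stats::rgamma(1, shape = pr$a, rate = pr$b)
  structure(list(log_alpha = stats::rnorm(1, pr$m, sqrt(s2 / pr$nu)),
                 sigma2 = s2), class = "clads_fixed")
}

# Draw one inheritance step (prior sample; commits the NIG update). Runs in
# the innermost loop, so the Student-t predictive draw and the conjugate
# update are inlined rather than routed through the validating API.
#' @noRd
clads_step <- function(shared) {
  car <- shared$step
  if (inherits(car, "clads_fixed")) {
    return(list(shared = shared,
                step = car$log_alpha + sqrt(car$sigma2) * rnorm(1)))
  }
  m0 <- car$m; nu <- car$nu; a <- car$a; b <- car$b
  x <- m0 + sqrt(b * (nu + 1) / (a * nu)) * rt(1, df = 2 * a)
  nu1 <- nu + 1
  car$m <- (nu * m0 + x) / nu1
  car$nu <- nu1
  car$a <- a + 0.5
  car$b <- b + nu * (x - m0)^2 / (2 * nu1)
  shared$step <- car
  list(shared = shared, step = x)
}

#' @noRd
lsbds_regime <- function(spec) {
  list(lam = make_rate_carrier(spec, "lambda"),
       mu = if (spec$lsbds_redraw_mu) make_rate_carrier(spec, "mu") else NULL)
}

#' @noRd
bamm_regime <- function(spec, shared, age) {
  list(lambda0 = realize_param(spec, "lambda"),
       mu = realize_param(spec, "mu"),
       z = realize_param(spec, "z"),
       t_ref = if (spec$bamm_reset_clock) age else shared$t0)
}

# ---------------------------------------------------------------------------

#' Simulate the hidden process along one observed branch
#'
#' Walks a lineage from `from_age` down to `to_age`, simulating hidden
#' speciation events (each spawning a side subtree that must leave no sampled
#' descendant) and, for the episodic models, rate-switch events; accumulates
#' the log-weight of the observed non-events (no extinction of the lineage)
#' and of the side-subtree outcomes.
#'
#' @param spec a `model_spec`.
#' @param state `list(shared =, lin =)` as produced by
#'   [init_particle_state()] / [observed_node_factor()].
#' @param from_age,to_age branch endpoints, `from_age >= to_age >= 0`.
#' @return `list(state =, dlw =, dead =)`; `dlw = -Inf` and `dead = TRUE`
#'   when a hidden side branch is detected at the present under `rho = 1`.
#' @export
walk_branch <- function(spec, state, from_age, to_age, warn = TRUE) {
  if (to_age < -1e-12 || from_age < to_age - 1e-12) {
    stop_domain("walk_branch requires from_age >= to_age >= 0")
  }
  if (from_age - to_age <= 0) return(list(state = state, dlw = 0, dead = FALSE))
  switch(spec$model,
    CRB = , CRBD = walk_crbd(spec, state, from_age, to_age, warn),
    TDB = , TDBD = walk_tdbd(spec, state, from_age, to_age, warn),
    ClaDS0 = , ClaDS1 = , ClaDS2 = walk_clads(spec, state, from_age, to_age, warn),
    LSBDS = walk_lsbds(spec, state, from_age, to_age, warn),
    BAMM = walk_bamm(spec, state, from_age, to_age, warn))
}

#' @noRd
walk_dead <- function(state) list(state = state, dlw = -Inf, dead = TRUE)

#' @noRd
walk_crbd <- function(spec, state, from, to, warn = TRUE) {
  sh <- state$shared
  dlw <- 0
  if (spec$model == "CRB" && spec$rho == 1) {
    # any hidden speciation would survive: condition on zero hidden events
    r <- carrier_surv(sh$lam, 1, from - to)
    return(list(state = list(shared = list(lam = r$car, mu = sh$mu), lin = NULL),
                dlw = r$lm, dead = FALSE))
  }
  cur <- from
  repeat {
    rem <- cur - to
    w <- carrier_wait(sh$lam, 1)
    if (w >= rem) {
      sh$lam <- carrier_commit(sh$lam, 1, rem, FALSE)
      r <- carrier_surv(sh$mu, 1, rem); sh$mu <- r$car; dlw <- dlw + r$lm
      break
    }
    sh$lam <- carrier_commit(sh$lam, 1, w, TRUE)
    r <- carrier_surv(sh$mu, 1, w); sh$mu <- r$car; dlw <- dlw + r$lm
    cur <- cur - w
    dlw <- dlw + log(2)
    hs <- hidden_subtree_outcome(spec, list(shared = sh, lin = NULL), cur, warn)
    sh <- hs$state$shared
    if (hs$dead) return(walk_dead(list(shared = sh, lin = NULL)))
    dlw <- dlw + hs$dlw
  }
  list(state = list(shared = sh, lin = NULL), dlw = dlw, dead = FALSE)
}

#' @noRd
walk_tdbd <- function(spec, state, from, to, warn = TRUE) {
  sh <- state$shared
  dlw <- 0
  if (spec$model == "TDB" && spec$rho == 1) {
    dlw <- -tdbd_intensity(sh$lambda0, sh$z, sh$t0, from, to)
    return(list(state = state, dlw = dlw, dead = FALSE))
  }
  cur <- from
  repeat {
    rem <- cur - to
    w <- tdbd_wait(sh$lambda0, sh$z, sh$t0, cur)
    tau <- min(w, rem)
    dlw <- dlw - sh$eps * tdbd_intensity(sh$lambda0, sh$z, sh$t0, cur, cur - tau)
    if (w >= rem) break
    cur <- cur - w
    dlw <- dlw + log(2)
    hs <- hidden_subtree_outcome(spec, list(shared = sh, lin = NULL), cur, warn)
    if (hs$dead) return(walk_dead(state))
    dlw <- dlw + hs$dlw
  }
  list(state = list(shared = sh, lin = NULL), dlw = dlw, dead = FALSE)
}

#' @noRd
walk_clads <- function(spec, state, from, to, warn = TRUE) {
  sh <- state$shared
  m <- state$lin$m
  dlw <- 0
  if (spec$model == "ClaDS0" && spec$rho == 1) {
    r <- carrier_surv(sh$lam0, m, from - to)
    sh$lam0 <- r$car
    return(list(state = list(shared = sh, lin = state$lin), dlw = r$lm, dead = FALSE))
  }
  cur <- from
  repeat {
    # a multiplier beyond ~1e12 means an astronomical diversification rate:
    # the lineage would spawn unbounded hidden side branches, essentially
    # none of which can avoid detection, so the particle is dead
    if (!is.finite(m) || m > 1e12) {
      return(walk_dead(list(shared = sh, lin = list(m = m))))
    }
    rem <- cur - to
    w <- carrier_wait(sh$lam0, m)
    tau <- min(w, rem)
    event <- w < rem
    sh$lam0 <- carrier_commit(sh$lam0, m, tau, event)
    if (spec$model != "ClaDS0") {
      r <- carrier_surv(sh$mu, if (spec$model == "ClaDS2") m else 1, tau)
      sh$mu <- r$car; dlw <- dlw + r$lm
    }
    if (!event) break
    cur <- cur - w
    dlw <- dlw + log(2)
    s1 <- clads_step(sh); sh <- s1$shared
    s2 <- clads_step(sh); sh <- s2$shared
    hs <- hidden_subtree_outcome(spec, list(shared = sh, lin = list(m = m * exp(s1$step))), cur, warn)
    sh <- hs$state$shared
    if (hs$dead) return(walk_dead(list(shared = sh, lin = list(m = m))))
    dlw <- dlw + hs$dlw
    m <- m * exp(s2$step)
  }
  list(state = list(shared = sh, lin = list(m = m)), dlw = dlw, dead = FALSE)
}

#' @noRd
walk_lsbds <- function(spec, state, from, to, warn = TRUE) {
  sh <- state$shared
  rid <- state$lin$regime
  dlw <- 0
  cur <- from
  repeat {
    rem <- cur - to
    reg <- sh$regimes[[rid]]
    wl <- carrier_wait(reg$lam, 1)
    ws <- carrier_wait(sh$eta, 1)
    tau <- min(wl, ws, rem)
    ev_l <- (tau < rem) && (wl <= ws)
    ev_s <- (tau < rem) && !ev_l
    reg$lam <- carrier_commit(reg$lam, 1, tau, ev_l)
    sh$eta <- carrier_commit(sh$eta, 1, tau, ev_s)
    if (is.null(reg$mu)) {
      r <- carrier_surv(sh$mu, 1, tau); sh$mu <- r$car
    } else {
      r <- carrier_surv(reg$mu, 1, tau); reg$mu <- r$car
    }
    dlw <- dlw + r$lm
    sh$regimes[[rid]] <- reg
    if (!ev_l && !ev_s) break
    cur <- cur - tau
    if (ev_l) {
      dlw <- dlw + log(2)
      hs <- hidden_subtree_outcome(spec, list(shared = sh, lin = list(regime = rid)), cur, warn)
      sh <- hs$state$shared
      if (hs$dead) return(walk_dead(list(shared = sh, lin = state$lin)))
      dlw <- dlw + hs$dlw
    } else {
      sh$regimes[[length(sh$regimes) + 1L]] <- lsbds_regime(spec)
      rid <- length(sh$regimes)
    }
  }
  list(state = list(shared = sh, lin = list(regime = rid)), dlw = dlw, dead = FALSE)
}

#' @noRd
walk_bamm <- function(spec, state, from, to, warn = TRUE) {
  sh <- state$shared
  lin <- state$lin
  dlw <- 0
  cur <- from
  repeat {
    rem <- cur - to
    wl <- tdbd_wait(lin$lambda0, lin$z, lin$t_ref, cur)
    ws <- carrier_wait(sh$eta, 1)
    tau <- min(wl, ws, rem)
    ev_l <- (tau < rem) && (wl <= ws)
    ev_s <- (tau < rem) && !ev_l
    sh$eta <- carrier_commit(sh$eta, 1, tau, ev_s)
    dlw <- dlw - lin$mu * tau
    if (!ev_l && !ev_s) break
    cur <- cur - tau
    if (ev_l) {
      dlw <- dlw + log(2)
      hs <- hidden_subtree_outcome(spec, list(shared = sh, lin = lin), cur, warn)
      sh <- hs$state$shared
      if (hs$dead) return(walk_dead(list(shared = sh, lin = lin)))
      dlw <- dlw + hs$dlw
    } else {
      lin <- bamm_regime(spec, sh, cur)
    }
  }
  list(state = list(shared = sh, lin = lin), dlw = dlw, dead = FALSE)
}

# ---------------------------------------------------------------------------

#' Forward-simulate a hidden side lineage to extinction or the present
#'
#' The side lineage born at `start_age` evolves under the model's own
#' dynamics (hidden speciations, extinctions, switches, ClaDS rate
#' inheritance). Each of its descendants surviving to the present must be
#' unsampled: with `rho < 1` that contributes `log(1 - rho)` per surviving
#' tip; with `rho = 1` a single survivor makes the particle dead. Extinct
#' subtrees contribute 0.
#'
#' @param spec a `model_spec`.
#' @param state `list(shared =, lin =)`; `lin` is the side lineage's state.
#' @param start_age age at which the side lineage is born.
#' @param warn emit a warning when the hidden-lineage cap is exceeded
#'   (the particle is then declared dead).
#' @return `list(state =, dlw =, dead =)`; `state$shared` carries any belief
#'   updates made during the simulation.
#' @export
hidden_subtree_outcome <- function(spec, state, start_age, warn = TRUE) {
  if (start_age < 0) stop_domain("start_age must be nonnegative")
  # flattened fast paths for the two families that dominate runtime; they
  # reproduce the generic event loop (same draw sequence) with scalar state
  if (spec$family == "crbd") {
    return(hidden_subtree_crbd(spec, state, start_age, warn))
  }
  if (spec$family == "clads") {
    return(hidden_subtree_clads(spec, state, start_age, warn))
  }
  sh <- state$shared
  dlw <- 0
  log1mrho <- if (spec$rho < 1) log1p(-spec$rho) else -Inf
  fam <- spec$family
  stack <- list(list(age = start_age, lin = state$lin))
  n_proc <- 0L
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    age <- top$age
    lin <- top$lin
    alive <- TRUE
    while (alive) {
      n_proc <- n_proc + 1L
      if (n_proc > spec$hidden_cap) {
        if (warn) warning("hidden-lineage cap exceeded; particle declared dead",
                          call. = FALSE)
        return(list(state = list(shared = sh, lin = state$lin), dlw = -Inf, dead = TRUE))
      }
      ev <- hidden_next_event(spec, sh, lin, age)
      sh <- ev$sh
      lin <- ev$lin
      if (ev$type == "present") {
        if (spec$rho == 1) {
          return(list(state = list(shared = sh, lin = state$lin), dlw = -Inf, dead = TRUE))
        }
        dlw <- dlw + log1mrho
        # exp(dlw) underflows to exactly 0 below ~-745: the particle weight
        # is already 0 in double precision, so declare it dead and stop
        if (dlw < -745) {
          return(list(state = list(shared = sh, lin = state$lin), dlw = -Inf, dead = TRUE))
        }
        alive <- FALSE
      } else if (ev$type == "extinction") {
        alive <- FALSE
      } else if (ev$type == "speciation") {
        age <- age - ev$tau
        if (fam == "clads") {
          s1 <- clads_step(sh); sh <- s1$shared
          s2 <- clads_step(sh); sh <- s2$shared
          m1 <- lin$m * exp(s1$step)
          m2 <- lin$m * exp(s2$step)
          # a runaway multiplier means an effectively infinite event rate:
          # the sub-population explodes and cannot stay undetected
          if (!is.finite(m1) || !is.finite(m2) || max(m1, m2) > 1e12) {
            return(list(state = list(shared = sh, lin = state$lin), dlw = -Inf, dead = TRUE))
          }
          stack[[length(stack) + 1L]] <- list(age = age, lin = list(m = m1))
          lin <- list(m = m2)
        } else {
          stack[[length(stack) + 1L]] <- list(age = age, lin = lin)
        }
      } else { # switch
        age <- age - ev$tau
        if (fam == "lsbds") {
          sh$regimes[[length(sh$regimes) + 1L]] <- lsbds_regime(spec)
          lin <- list(regime = length(sh$regimes))
        } else {
          lin <- bamm_regime(spec, sh, age)
        }
      }
    }
  }
  list(state = list(shared = sh, lin = state$lin), dlw = dlw, dead = FALSE)
}

# Flattened CRB(D) hidden-subtree simulation: scalar belief fields, numeric
# stack. Draw-for-draw equivalent to the generic event loop.
#' @noRd
hidden_subtree_crbd <- function(spec, state, start_age, warn) {
  sh <- state$shared
  rho1 <- spec$rho == 1
  log1mrho <- if (!rho1) log1p(-spec$rho) else -Inf
  cap <- spec$hidden_cap
  lam_b <- is.list(sh$lam)
  if (lam_b) { kl <- sh$lam$k; bl <- sh$lam$beta } else lamv <- sh$lam
  mu_b <- is.list(sh$mu)
  if (mu_b) { km <- sh$mu$k; bm <- sh$mu$beta } else muv <- sh$mu
  finish <- function(dlw, dead) {
    if (lam_b) { sh$lam$k <- kl; sh$lam$beta <- bl }
    if (mu_b) { sh$mu$k <- km; sh$mu$beta <- bm }
    list(state = list(shared = sh, lin = state$lin), dlw = dlw, dead = dead)
  }
  dlw <- 0
  stack <- c(start_age)
  np <- 0L
  while (length(stack)) {
    age <- stack[length(stack)]
    stack <- stack[-length(stack)]
    repeat {
      np <- np + 1L
      if (np > cap) {
        if (warn) warning("hidden-lineage cap exceeded; particle declared dead",
                          call. = FALSE)
        return(finish(-Inf, TRUE))
      }
      wl <- if (lam_b) bl * (runif(1)^(-1 / kl) - 1)
            else if (lamv > 0) rexp(1, lamv) else Inf
      wm <- if (mu_b) bm * (runif(1)^(-1 / km) - 1)
            else if (muv > 0) rexp(1, muv) else Inf
      tau <- min(wl, wm, age)
      ev_l <- (tau < age) && (wl <= wm)
      ev_m <- (tau < age) && !ev_l
      if (lam_b) { bl <- bl + tau; if (ev_l) kl <- kl + 1 }
      if (mu_b) { bm <- bm + tau; if (ev_m) km <- km + 1 }
      if (tau >= age) { # present
        if (rho1) return(finish(-Inf, TRUE))
        dlw <- dlw + log1mrho
        if (dlw < -745) return(finish(-Inf, TRUE))
        break
      }
      age <- age - tau
      if (ev_m) break # extinction
      stack[length(stack) + 1L] <- age # speciation: sibling, same state
    }
  }
  finish(dlw, FALSE)
}

# Flattened ClaDS hidden-subtree simulation (all three variants).
#' @noRd
hidden_subtree_clads <- function(spec, state, start_age, warn) {
  sh <- state$shared
  model <- spec$model
  rho1 <- spec$rho == 1
  log1mrho <- if (!rho1) log1p(-spec$rho) else -Inf
  cap <- spec$hidden_cap
  lam_b <- is.list(sh$lam0)
  if (lam_b) { kl <- sh$lam0$k; bl <- sh$lam0$beta } else lamv <- sh$lam0
  step_b <- !inherits(sh$step, "clads_fixed")
  if (step_b) {
    nm <- sh$step$m; nnu <- sh$step$nu; na <- sh$step$a; nb <- sh$step$b
  } else {
    la <- sh$step$log_alpha; ssd <- sqrt(sh$step$sigma2)
  }
  is2 <- model == "ClaDS2"
  has_mu <- model != "ClaDS0"
  if (has_mu) {
    mu_b <- is.list(sh$mu)
    if (mu_b) { km <- sh$mu$k; bm <- sh$mu$beta } else muv <- sh$mu
  }
  finish <- function(dlw, dead) {
    if (lam_b) { sh$lam0$k <- kl; sh$lam0$beta <- bl }
    if (step_b) {
      sh$step$m <- nm; sh$step$nu <- nnu; sh$step$a <- na; sh$step$b <- nb
    }
    if (has_mu && mu_b) { sh$mu$k <- km; sh$mu$beta <- bm }
    list(state = list(shared = sh, lin = state$lin), dlw = dlw, dead = dead)
  }
  draw_step <- function() {
    if (!step_b) return(la + ssd * rnorm(1))
    m0 <- nm
    x <- m0 + sqrt(nb * (nnu + 1) / (na * nnu)) * rt(1, df = 2 * na)
    nu1 <- nnu + 1
    nm <<- (nnu * m0 + x) / nu1
    nb <<- nb + nnu * (x - m0)^2 / (2 * nu1)
    nnu <<- nu1
    na <<- na + 0.5
    x
  }
  dlw <- 0
  ages <- c(start_age)
  ms <- c(state$lin$m)
  np <- 0L
  while (length(ages)) {
    i <- length(ages)
    age <- ages[i]; m <- ms[i]
    ages <- ages[-i]; ms <- ms[-i]
    repeat {
      np <- np + 1L
      if (np > cap) {
        if (warn) warning("hidden-lineage cap exceeded; particle declared dead",
                          call. = FALSE)
        return(finish(-Inf, TRUE))
      }
      mu_mult <- if (is2) m else 1
      wl <- if (lam_b) bl * (runif(1)^(-1 / kl) - 1) / m
            else if (m * lamv > 0) rexp(1, m * lamv) else Inf
      wm <- if (!has_mu) Inf
            else if (mu_b) bm * (runif(1)^(-1 / km) - 1) / mu_mult
            else if (mu_mult * muv > 0) rexp(1, mu_mult * muv) else Inf
      tau <- min(wl, wm, age)
      ev_l <- (tau < age) && (wl <= wm)
      ev_m <- (tau < age) && !ev_l
      if (lam_b) {
        ct <- m * tau
        if (is.finite(ct)) bl <- bl + ct
        if (ev_l) kl <- kl + 1
      }
      if (has_mu && mu_b) {
        ct <- mu_mult * tau
        if (is.finite(ct)) bm <- bm + ct
        if (ev_m) km <- km + 1
      }
      type <- if (ev_l) 1L else if (ev_m) 2L else 0L
      if (type == 0L) { # present
        if (rho1) return(finish(-Inf, TRUE))
        dlw <- dlw + log1mrho
        if (dlw < -745) return(finish(-Inf, TRUE))
        break
      }
      age <- age - tau
      if (type == 2L) break # extinction
      # speciation: both daughters draw inheritance steps
      s1 <- draw_step()
      s2 <- draw_step()
      m1 <- m * exp(s1)
      m2 <- m * exp(s2)
      if (!is.finite(m1) || !is.finite(m2) || max(m1, m2) > 1e12) {
        return(finish(-Inf, TRUE))
      }
      i <- length(ages) + 1L
      ages[i] <- age; ms[i] <- m1
      m <- m2
    }
  }
  finish(dlw, FALSE)
}

# Draw the next event for one hidden lineage at `age` (time runs toward the
# present; the horizon is the present itself). Commits belief updates for
# the winning event and the exposures of the losers. Returns
# list(tau, type, sh, lin) with type in {"speciation", "extinction",
# "switch", "present"}.
#' @noRd
hidden_next_event <- function(spec, sh, lin, age) {
  fam <- spec$family
  if (fam == "crbd") {
    wl <- carrier_wait(sh$lam, 1)
    wm <- carrier_wait(sh$mu, 1)
    tau <- min(wl, wm, age)
    ev_l <- (tau < age) && (wl <= wm)
    ev_m <- (tau < age) && !ev_l
    sh$lam <- carrier_commit(sh$lam, 1, tau, ev_l)
    sh$mu <- carrier_commit(sh$mu, 1, tau, ev_m)
    type <- if (ev_l) "speciation" else if (ev_m) "extinction" else "present"
  } else if (fam == "tdbd") {
    wl <- tdbd_wait(sh$lambda0, sh$z, sh$t0, age)
    wm <- if (sh$eps > 0) tdbd_wait(sh$eps * sh$lambda0, sh$z, sh$t0, age) else Inf
    tau <- min(wl, wm, age)
    ev_l <- (tau < age) && (wl <= wm)
    ev_m <- (tau < age) && !ev_l
    type <- if (ev_l) "speciation" else if (ev_m) "extinction" else "present"
  } else if (fam == "clads") {
    mu_mult <- if (spec$model == "ClaDS2") lin$m else 1
    wl <- carrier_wait(sh$lam0, lin$m)
    wm <- if (spec$model == "ClaDS0") Inf else carrier_wait(sh$mu, mu_mult)
    tau <- min(wl, wm, age)
    ev_l <- (tau < age) && (wl <= wm)
    ev_m <- (tau < age) && !ev_l
    sh$lam0 <- carrier_commit(sh$lam0, lin$m, tau, ev_l)
    if (spec$model != "ClaDS0") sh$mu <- carrier_commit(sh$mu, mu_mult, tau, ev_m)
    type <- if (ev_l) "speciation" else if (ev_m) "extinction" else "present"
  } else if (fam == "lsbds") {
    reg <- sh$regimes[[lin$regime]]
    mu_car <- if (is.null(reg$mu)) sh$mu else reg$mu
    wl <- carrier_wait(reg$lam, 1)
    wm <- carrier_wait(mu_car, 1)
    ws <- carrier_wait(sh$eta, 1)
    tau <- min(wl, wm, ws, age)
    ev_l <- (tau < age) && (wl <= wm) && (wl <= ws)
    ev_m <- (tau < age) && !ev_l && (wm <= ws)
    ev_s <- (tau < age) && !ev_l && !ev_m
    reg$lam <- carrier_commit(reg$lam, 1, tau, ev_l)
    mu_new <- carrier_commit(mu_car, 1, tau, ev_m)
    if (is.null(reg$mu)) sh$mu <- mu_new else reg$mu <- mu_new
    sh$eta <- carrier_commit(sh$eta, 1, tau, ev_s)
    sh$regimes[[lin$regime]] <- reg
    type <- if (ev_l) "speciation" else if (ev_m) "extinction"
            else if (ev_s) "switch" else "present"
  } else { # BAMM
    wl <- tdbd_wait(lin$lambda0, lin$z, lin$t_ref, age)
    wm <- if (lin$mu > 0) stats::rexp(1, lin$mu) else Inf
    ws <- carrier_wait(sh$eta, 1)
    tau <- min(wl, wm, ws, age)
    ev_l <- (tau < age) && (wl <= wm) && (wl <= ws)
    ev_m <- (tau < age) && !ev_l && (wm <= ws)
    ev_s <- (tau < age) && !ev_l && !ev_m
    sh$eta <- carrier_commit(sh$eta, 1, tau, ev_s)
    type <- if (ev_l) "speciation" else if (ev_m) "extinction"
            else if (ev_s) "switch" else "present"
  }
  list(tau = tau, type = type, sh = sh, lin = lin)
}

# ---------------------------------------------------------------------------

#' Weight factor and child states at an observed speciation node
#'
#' Adds the log marginal speciation intensity at the node's age (a gamma
#' event update when the rate is delayed) and produces the two daughter
#' lineage states according to the model's inheritance semantics (ClaDS
#' daughters draw fresh lognormal steps; episodic models pass the regime on).
#'
#' @param spec a `model_spec`.
#' @param state `list(shared =, lin =)` of the branch ending at the node.
#' @param node_age age of the observed speciation event.
#' @return `list(state =, children =, dlw =)`; `children` is a list of two
#'   `lin` states.
#' @export
observed_node_factor <- function(spec, state, node_age) {
  sh <- state$shared
  lin <- state$lin
  model <- spec$model
  if (model %in% c("CRB", "CRBD")) {
    r <- carrier_event(sh$lam, 1)
    sh$lam <- r$car
    return(list(state = list(shared = sh, lin = NULL),
                children = list(NULL, NULL), dlw = r$lm))
  }
  if (model %in% c("TDB", "TDBD")) {
    lam <- lambda_t(sh$lambda0, sh$z, sh$t0, node_age)
    return(list(state = state, children = list(NULL, NULL),
                dlw = if (lam > 0) log(lam) else -Inf))
  }
  if (model %in% c("ClaDS0", "ClaDS1", "ClaDS2")) {
    r <- carrier_event(sh$lam0, lin$m)
    sh$lam0 <- r$car
    s1 <- clads_step(sh); sh <- s1$shared
    s2 <- clads_step(sh); sh <- s2$shared
    return(list(state = list(shared = sh, lin = NULL),
                children = list(list(m = lin$m * exp(s1$step)),
                                list(m = lin$m * exp(s2$step))),
                dlw = r$lm))
  }
  if (model == "LSBDS") {
    reg <- sh$regimes[[lin$regime]]
    r <- carrier_event(reg$lam, 1)
    reg$lam <- r$car
    sh$regimes[[lin$regime]] <- reg
    return(list(state = list(shared = sh, lin = NULL),
                children = list(lin, lin), dlw = r$lm))
  }
  # BAMM
  lam <- lambda_t(lin$lambda0, lin$z, lin$t_ref, node_age)
  list(state = list(shared = sh, lin = NULL), children = list(lin, lin),
       dlw = if (lam > 0) log(lam) else -Inf)
}

#' Weight factor at an observed tip
#'
#' Every observed tip was sampled, an event of probability `rho`.
#'
#' @param spec a `model_spec`.
#' @param rho sampling probability (defaults to the spec's).
#' @return `log(rho)`.
#' @export
tip_factor <- function(spec, rho = spec$rho) log(rho)

#' Orientation correction
#'
#' The simulation generates ordered (oriented) outcomes: one orientation
#' choice per observed internal node. Adding `(n - 1) log 2` once converts
#' the estimate to the labeled, unordered convention. The constant is
#' model-independent, so Bayes factors are unaffected.
#'
#' @param tree observed `time_tree` with n leaves.
#' @return `(n - 1) * log(2)`.
#' @export
orientation_correction <- function(tree) (tree$n_tips - 1) * log(2)

#' Survivorship-bias correction
#'
#' Observed clades necessarily survived: conditioning on both crown lineages
#' leaving at least one sampled descendant subtracts
#' `log P(crown survival)` from the log marginal likelihood. The probability
#' is computed in closed form for fixed-parameter CRB/CRBD and otherwise by
#' forward-simulation Monte Carlo (one parameter realization per call,
#' `n_mc` crown survival replicates).
#'
#' @param spec a `model_spec`.
#' @param t0 crown age.
#' @param n_mc Monte Carlo replicates (>= 1).
#' @param force_mc use the Monte Carlo route even when the closed form applies.
#' @return The correction `-log P(both crown lineages survive)`, to be added
#'   to the log marginal likelihood.
#' @export
survivorship_correction <- function(spec, t0, n_mc = 1000, force_mc = FALSE) {
  if (n_mc < 1) stop_domain("n_mc must be >= 1")
  if (t0 <= 0) stop_domain("t0 must be positive")
  closed <- spec$model %in% c("CRB", "CRBD") && !is.null(spec$fixed$lambda) &&
    (spec$model == "CRB" || !is.null(spec$fixed$mu))
  if (closed && !force_mc) {
    p <- crbd_params(spec$fixed$lambda,
                     if (spec$model == "CRBD") spec$fixed$mu else 0, spec$rho)
    return(-2 * log1p(-extinction_prob_crbd(p, t0)))
  }
  espec <- spec
  espec$delayed <- FALSE
  st <- init_particle_state(espec, t0)
  hits <- 0L
  for (i in seq_len(n_mc)) {
    hits <- hits + (lineage_detected(espec, st, t0) && lineage_detected(espec, st, t0))
  }
  if (hits == 0L) stop("survivorship Monte Carlo observed no surviving crowns; increase n_mc",
                       call. = FALSE)
  -log(hits / n_mc)
}

# Does a lineage starting at `age` leave at least one sampled descendant?
# Reuses the hidden-subtree simulator: its weight is log((1-rho)^k) with k
# surviving tips, so detection occurs with probability 1 - exp(dlw).
#' @noRd
lineage_detected <- function(spec, state, age) {
  r <- hidden_subtree_outcome(spec, state, age, warn = FALSE)
  if (r$dead) return(TRUE) # rho = 1 survivor, or cap blowup (treated as detected)
  if (spec$rho == 1) return(FALSE)
  stats::runif(1) < 1 - exp(r$dlw)
}
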
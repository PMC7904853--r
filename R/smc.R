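# Inference engines.
#
# run_smc: bootstrap particle filter with resampling aligned at the observed
#   tree's checkpoints (every particle has processed the same portion of the
#   tree whenever particles are compared).
# run_apf: alive particle filter — at each checkpoint ancestors are redrawn
#   and propagated until N alive (nonzero-weight) particles are collected;
#   the attempt count A_t enters the unbiased inverse-binomial correction
#   (N-1)/(A_t-1). With no deaths it collapses to multinomial SMC exactly.
# run_importance_sampling: importance sampling against the closed-form
#   likelihood for CRB/CRBD/TDB/TDBD.
#
# All engines accumulate log Z as the sum over checkpoints of the log mean
# unnormalized incremental weight, add the orientation constant, and report
# per-checkpoint diagnostics.

#' @noRd
tree_signature <- function(tree) {
  c(tree$n_tips, round(sum(tree$age), 9), round(tree$age[tree$root], 9))
}

# Propagate one particle through one non-root checkpoint.
# Returns list(particle, dlw).
#' @noRd
step_particle <- function(spec, tree, particle, node, node_age, parent_age, is_leaf) {
  # the constant-rate families carry no per-lineage state, so their pending
  # bookkeeping is skipped entirely; other families store the lineage state
  # wrapped in a length-1 list (a bare NULL would delete the entry)
  stateless <- spec$family == "crbd" || spec$family == "tdbd"
  if (stateless) {
    lin <- NULL
  } else {
    key <- as.character(node)
    lin <- particle$pending[[key]][[1]]
    particle$pending[[key]] <- NULL
  }
  r <- walk_branch(spec, list(shared = particle$shared, lin = lin),
                   parent_age, node_age, warn = FALSE)
  particle$shared <- r$state$shared
  if (r$dead) return(list(particle = particle, dlw = -Inf))
  dlw <- r$dlw
  if (is_leaf) {
    dlw <- dlw + tip_factor(spec)
  } else {
    nf <- observed_node_factor(spec, r$state, node_age)
    particle$shared <- nf$state$shared
    if (!stateless) {
      kids <- tree$children[node, ]
      particle$pending[[as.character(kids[1])]] <- list(nf$children[[1]])
      particle$pending[[as.character(kids[2])]] <- list(nf$children[[2]])
    }
    dlw <- dlw + nf$dlw
  }
  list(particle = particle, dlw = dlw)
}

# Fixed-parameter CRB(D) particles carry no state, so a whole cohort can be
# propagated through a checkpoint in one vectorized pass: Poisson counts of
# hidden speciations per particle, then scalar side-subtree simulations for
# the (few) particles with events.
#' @noRd
is_fixed_crbd <- function(spec) {
  spec$model %in% c("CRB", "CRBD") && !is.null(spec$fixed$lambda) &&
    (spec$model == "CRB" || !is.null(spec$fixed$mu))
}

#' @noRd
batch_lw_fixed_crbd <- function(spec, n, node_age, parent_age, is_leaf) {
  lam <- spec$fixed$lambda
  mu <- if (spec$model == "CRBD") spec$fixed$mu else 0
  rho <- spec$rho
  d <- parent_age - node_age
  lw <- numeric(n)
  if (d > 0) {
    if (mu == 0 && rho == 1) {
      lw <- lw - lam * d
    } else {
      lw <- lw - mu * d
      k <- rpois(n, lam * d)
      tot <- sum(k)
      if (tot > 0) {
        owner <- rep.int(seq_len(n), k)
        ages <- node_age + runif(tot) * d
        sub <- crbd_subtrees_batch(lam, mu, rho, ages)
        lw <- lw + log(2) * k
        contrib <- sub$dlw
        contrib[sub$dead] <- -Inf
        s <- rowsum(contrib, owner)
        idx <- as.integer(rownames(s))
        lw[idx] <- lw[idx] + s[, 1]
      }
    }
  }
  lw + if (is_leaf) log(rho) else if (lam > 0) log(lam) else -Inf
}

# Simulate many CRBD side subtrees at once (vectorized frontier, one entry
# per live lineage): each subtree born at `ages[i]` either goes extinct
# entirely (contribution of its surviving-tip count, 0 under full
# extinction) or is detected. Under rho = 1 any surviving tip is detection;
# under rho < 1 the subtree contributes tips * log(1 - rho), truncated to
# dead once that factor is below the double-precision floor.
#' @noRd
crbd_subtrees_batch <- function(lam, mu, rho, ages) {
  m <- length(ages)
  dead <- logical(m)
  tips <- integer(m)
  tip_cap <- if (rho < 1) ceiling(745 / max(-log1p(-rho), 1e-6)) else 0L
  id <- seq_len(m)
  age <- ages
  total <- lam + mu
  p_spec <- lam / total
  while (length(age)) {
    w <- rexp(length(age), total)
    reach <- w >= age
    if (any(reach)) {
      tips <- tips + tabulate(id[reach], m)
      if (rho == 1) dead[tips > 0L] <- TRUE else dead[tips > tip_cap] <- TRUE
    }
    keep <- !reach & !dead[id]
    age2 <- age[keep] - w[keep]
    id2 <- id[keep]
    sp <- runif(length(age2)) < p_spec
    age <- c(age2[sp], age2[sp])
    id <- c(id2[sp], id2[sp])
  }
  list(dead = dead,
       dlw = if (rho < 1) tips * log1p(-rho) else numeric(m))
}

#' @noRd
init_particles <- function(spec, tree, n) {
  t0 <- tree$age[tree$root]
  kids <- tree$children[tree$root, ]
  stateless <- spec$family == "crbd" || spec$family == "tdbd"
  lapply(seq_len(n), function(i) {
    st <- init_particle_state(spec, t0)
    p <- list(shared = st$shared, pending = list())
    if (!stateless) {
      p$pending[[as.character(kids[1])]] <- list(st$lin)
      p$pending[[as.character(kids[2])]] <- list(st$lin)
    }
    p
  })
}

#' @noRd
new_smc_result <- function(spec, tree, log_z, weights, particles, diagnostics,
                           n_particles, seed, engine) {
  structure(list(log_z = log_z, weights = weights, particles = particles,
                 diagnostics = diagnostics, n_particles = n_particles,
                 seed = seed, engine = engine, model = spec$model,
                 tree_signature = tree_signature(tree)),
            class = "smc_result")
}

#' @export
print.smc_result <- function(x, ...) {
  cat(sprintf("smc_result [%s, %s]: log Z = %.4f (N = %d)\n",
              x$engine, x$model, x$log_z, x$n_particles))
  invisible(x)
}

#' Resample particle indices
#'
#' @param weights nonnegative particle weights (natural scale).
#' @param n number of ancestors to draw.
#' @param scheme `"multinomial"` or `"systematic"`.
#' @return Integer ancestor indices; expected offspring count of particle i
#'   is `n * w_i / sum(w)`.
#' @export
resample <- function(weights, n = length(weights),
                     scheme = c("systematic", "multinomial")) {
  scheme <- match.arg(scheme)
  if (!any(weights > 0)) stop_domain("resample requires a positive weight")
  if (scheme == "multinomial") {
    sample.int(length(weights), n, replace = TRUE, prob = weights)
  } else {
    w <- weights / sum(weights)
    u <- (stats::runif(1) + seq_len(n) - 1) / n
    # guard the floating-point case cumsum(w)[m] < u < 1
    pmin(findInterval(u, cumsum(w)) + 1L, length(weights))
  }
}

#' Relative effective sample size
#'
#' `(sum w)^2 / (N sum w^2)`, in (0, 1]; 1 for equal weights.
#'
#' @param weights nonnegative weights.
#' @return Relative ESS.
#' @export
relative_ess <- function(weights) {
  if (!any(weights > 0)) stop_domain("relative_ess requires a positive weight")
  sum(weights)^2 / (length(weights) * sum(weights^2))
}

#' Run the aligned bootstrap particle filter
#'
#' Propagates `n_particles` particles checkpoint to checkpoint through the
#' observed tree, adds `log(mean incremental weight)` to the log marginal
#' likelihood estimate at every checkpoint, and resamples (unconditionally
#' by default; set `ess_threshold < 1` to resample only when the relative
#' ESS drops below it). The final estimate includes the orientation
#' correction and, when the spec requests it, the survivorship correction.
#'
#' @param spec a `model_spec`.
#' @param tree observed ultrametric `time_tree`.
#' @param n_particles number of particles (>= 2).
#' @param schedule checkpoint schedule (defaults to [make_schedule()]).
#' @param resampler resampling scheme.
#' @param seed optional RNG seed for the run.
#' @param ess_threshold resample when relative ESS <= this (1 = always).
#' @param orientation include the orientation correction.
#' @param n_mc_survivorship Monte Carlo size for the survivorship correction
#'   when no closed form applies.
#' @return An `smc_result` with `log_z`, final normalized `weights`, final
#'   per-particle parameter states, and per-checkpoint `diagnostics`.
#' @export
run_smc <- function(spec, tree, n_particles, schedule = make_schedule(tree),
                    resampler = c("systematic", "multinomial"), seed = NULL,
                    ess_threshold = 1, orientation = TRUE,
                    n_mc_survivorship = 200) {
  resampler <- match.arg(resampler)
  if (n_particles < 2) stop_domain("need at least 2 particles")
  if (!is.null(seed)) set.seed(seed)
  n <- n_particles
  particles <- init_particles(spec, tree, n)
  steps <- schedule[schedule$type != "root", , drop = FALSE]
  k_steps <- nrow(steps)
  log_z <- 0
  ess <- numeric(k_steps)
  lw <- numeric(n)
  fast <- is_fixed_crbd(spec)
  for (i in seq_len(k_steps)) {
    node <- steps$node[i]
    is_leaf <- steps$type[i] == "leaf"
    if (fast) {
      lw <- batch_lw_fixed_crbd(spec, n, steps$age[i], steps$parent_age[i], is_leaf)
    } else {
      for (j in seq_len(n)) {
        r <- step_particle(spec, tree, particles[[j]], node, steps$age[i],
                           steps$parent_age[i], is_leaf)
        particles[[j]] <- r$particle
        lw[j] <- r$dlw
      }
    }
    if (i == k_steps && spec$survivorship) {
      lw <- lw + survivorship_lw(spec, tree, particles, n_mc_survivorship)
    }
    if (all(!is.finite(lw))) {
      stop(sprintf("all particles dead at checkpoint %d (node %d); consider run_apf",
                   i, node), call. = FALSE)
    }
    log_z <- log_z + log_mean_exp(lw)
    w <- norm_weights(lw)
    ess[i] <- relative_ess(w)
    if (i < k_steps && ess[i] <= ess_threshold) {
      idx <- resample(w, n, resampler)
      if (!fast) particles <- particles[idx]
    }
  }
  if (orientation) log_z <- log_z + orientation_correction(tree)
  diagnostics <- data.frame(checkpoint = seq_len(k_steps), node = steps$node,
                            relative_ess = ess, acceptance = 1)
  new_smc_result(spec, tree, log_z, norm_weights(lw), lapply(particles, `[[`, "shared"),
                 diagnostics, n, seed, "smc")
}

# Per-particle survivorship correction: -log P(both crown lineages leave a
# sampled descendant), estimated with the particle's own parameter
# realization (closed form for fixed-parameter CRB/CRBD).
#' @noRd
survivorship_lw <- function(spec, tree, particles, n_mc) {
  t0 <- tree$age[tree$root]
  closed <- spec$model %in% c("CRB", "CRBD") && !is.null(spec$fixed$lambda) &&
    (spec$model == "CRB" || !is.null(spec$fixed$mu))
  if (closed) {
    return(rep(survivorship_correction(spec, t0), length(particles)))
  }
  vapply(particles, function(sh) {
    espec <- realize_spec_from_shared(spec, sh)
    survivorship_correction(espec, t0, n_mc = n_mc)
  }, numeric(1))
}

# Turn a particle's shared state into a fully fixed spec (realizing beliefs),
# for survivorship Monte Carlo.
#' @noRd
realize_spec_from_shared <- function(spec, sh) {
  fx <- spec$fixed
  m <- spec$model
  if (m %in% c("CRB", "CRBD")) {
    fx$lambda <- carrier_realize(sh$lam)
    if (m == "CRBD") fx$mu <- carrier_realize(sh$mu)
  } else if (m %in% c("TDB", "TDBD")) {
    fx$lambda <- sh$lambda0; fx$z <- sh$z
    if (m == "TDBD") fx$eps <- sh$eps
  } else if (m %in% c("ClaDS0", "ClaDS1", "ClaDS2")) {
    fx$lambda <- carrier_realize(sh$lam0)
    if (inherits(sh$step, "clads_fixed")) {
      fx$log_alpha <- sh$step$log_alpha; fx$sigma2 <- sh$step$sigma2
    } else {
      s2 <- 1 / stats::rgamma(1, shape = sh$step$a, rate = sh$step$b)
      fx$log_alpha <- stats::rnorm(1, sh$step$m, sqrt(s2 / sh$step$nu))
      fx$sigma2 <- s2
    }
    if (m %in% c("ClaDS1", "ClaDS2")) fx$mu <- carrier_realize(sh$mu)
  } else if (m == "LSBDS") {
    fx$lambda <- carrier_realize(sh$regimes[[1]]$lam)
    fx$mu <- carrier_realize(sh$mu)
    fx$eta <- carrier_realize(sh$eta)
  } else { # BAMM
    rr <- sh$root_regime
    fx$lambda <- rr$lambda0; fx$mu <- rr$mu; fx$z <- rr$z
    fx$eta <- carrier_realize(sh$eta)
  }
  spec$fixed <- fx
  spec$delayed <- FALSE
  spec
}

#' Run the alive particle filter
#'
#' At each checkpoint, ancestors are drawn (multinomially, from the previous
#' alive weights) and propagated until `n_particles` alive particles are
#' collected; the total number of attempts `A_t` (including the draw that
#' produced the last alive particle) enters the unbiased increment
#' `log(mean alive weight) + log((N - 1) / (A_t - 1))`. When no particle
#' dies, `A_t = N` and the run is identical to multinomial [run_smc()]
#' under the same seed.
#'
#' @inheritParams run_smc
#' @param attempts_cap_factor abort when a checkpoint needs more than
#'   `attempts_cap_factor * n_particles` attempts.
#' @return An `smc_result`; `diagnostics$acceptance` holds the conditional
#'   acceptance rate `N / A_t` per checkpoint.
#' @export
run_apf <- function(spec, tree, n_particles, schedule = make_schedule(tree),
                    seed = NULL, orientation = TRUE, attempts_cap_factor = 1000,
                    n_mc_survivorship = 200) {
  if (n_particles < 2) stop_domain("need at least 2 particles")
  if (!is.null(seed)) set.seed(seed)
  n <- n_particles
  particles <- init_particles(spec, tree, n)
  steps <- schedule[schedule$type != "root", , drop = FALSE]
  k_steps <- nrow(steps)
  log_z <- 0
  ess <- numeric(k_steps)
  acc <- numeric(k_steps)
  prev_w <- rep(1 / n, n)
  cap <- attempts_cap_factor * n
  lw <- numeric(n)
  fast <- is_fixed_crbd(spec)
  for (i in seq_len(k_steps)) {
    node <- steps$node[i]
    is_leaf <- steps$type[i] == "leaf"
    new_particles <- vector("list", n)
    new_lw <- numeric(n)
    collected <- 0L
    attempts <- 0L
    first_batch <- TRUE
    while (collected < n) {
      need <- n - collected
      anc <- if (first_batch && i == 1L) seq_len(n)
             else sample.int(n, need, replace = TRUE, prob = prev_w)
      first_batch <- FALSE
      if (fast) {
        lwb <- batch_lw_fixed_crbd(spec, length(anc), steps$age[i],
                                   steps$parent_age[i], is_leaf)
        okk <- which(is.finite(lwb))
        if (length(okk) >= need) {
          new_lw[(collected + 1L):n] <- lwb[okk[seq_len(need)]]
          attempts <- attempts + okk[need]
          collected <- n
        } else {
          if (length(okk)) {
            new_lw[collected + seq_along(okk)] <- lwb[okk]
            collected <- collected + length(okk)
          }
          attempts <- attempts + length(anc)
        }
      } else {
        ok_pos <- 0L
        for (b in seq_along(anc)) {
          r <- step_particle(spec, tree, particles[[anc[b]]], node, steps$age[i],
                             steps$parent_age[i], is_leaf)
          if (is.finite(r$dlw)) {
            collected <- collected + 1L
            new_particles[[collected]] <- r$particle
            new_lw[collected] <- r$dlw
            ok_pos <- b
            if (collected == n) break
          }
        }
        attempts <- attempts + if (collected == n) ok_pos else length(anc)
      }
      if (attempts > cap && collected < n) {
        stop(sprintf("alive particle filter exceeded %d attempts at checkpoint %d (node %d)",
                     cap, i, node), call. = FALSE)
      }
    }
    if (fast) new_particles <- particles
    if (i == k_steps && spec$survivorship) {
      new_lw <- new_lw + survivorship_lw(spec, tree, new_particles, n_mc_survivorship)
    }
    log_z <- log_z + log_mean_exp(new_lw) + log(n - 1) - log(attempts - 1)
    lw <- new_lw
    particles <- new_particles
    prev_w <- norm_weights(lw)
    ess[i] <- relative_ess(prev_w)
    acc[i] <- n / attempts
  }
  if (orientation) log_z <- log_z + orientation_correction(tree)
  diagnostics <- data.frame(checkpoint = seq_len(k_steps), node = steps$node,
                            relative_ess = ess, acceptance = acc)
  new_smc_result(spec, tree, log_z, prev_w, lapply(particles, `[[`, "shared"),
                 diagnostics, n, seed, "apf")
}

#' Importance sampling with the closed-form likelihood
#'
#' For the four models with tractable likelihoods (CRB, CRBD, TDB, TDBD),
#' parameters are drawn from their priors and weighted by the analytic
#' likelihood of the observed tree; `log Z` is the log mean weight.
#'
#' @inheritParams run_smc
#' @return An `smc_result`; `particles` holds the drawn parameter sets.
#' @export
run_importance_sampling <- function(spec, tree, n_particles, seed = NULL,
                                    orientation = TRUE) {
  if (!spec$model %in% c("CRB", "CRBD", "TDB", "TDBD")) {
    stop_domain("no closed-form likelihood for model %s", spec$model)
  }
  if (n_particles < 1) stop_domain("need at least 1 particle")
  if (!is.null(seed)) set.seed(seed)
  n <- n_particles
  t0 <- tree$age[tree$root]
  draws <- vector("list", n)
  lw <- numeric(n)
  for (j in seq_len(n)) {
    lam <- realize_param(spec, "lambda")
    if (spec$model == "CRB") {
      lw[j] <- crbd_loglik(tree, crbd_params(lam, 0, spec$rho),
                           orientation = orientation,
                           survivorship = spec$survivorship)
      draws[[j]] <- list(lambda = lam)
    } else if (spec$model == "CRBD") {
      mu <- realize_param(spec, "mu")
      lw[j] <- crbd_loglik(tree, crbd_params(lam, mu, spec$rho),
                           orientation = orientation,
                           survivorship = spec$survivorship)
      draws[[j]] <- list(lambda = lam, mu = mu)
    } else {
      z <- realize_param(spec, "z")
      eps <- if (spec$model == "TDBD") realize_param(spec, "eps") else 0
      lw[j] <- tdbd_loglik(tree, lam, z, eps, spec$rho,
                           orientation = orientation,
                           survivorship = spec$survivorship)
      draws[[j]] <- list(lambda = lam, z = z, eps = eps)
    }
  }
  log_z <- log_mean_exp(lw)
  diagnostics <- data.frame(checkpoint = 1L, node = NA_integer_,
                            relative_ess = relative_ess(norm_weights(lw)),
                            acceptance = 1)
  new_smc_result(spec, tree, log_z, norm_weights(lw), draws, diagnostics,
                 n, seed, "is")
}

#' Log Bayes factor between two marginal-likelihood estimates
#'
#' `log Z_a - log Z_b` on the same tree. By convention a difference of 5 log
#' units is considered strong evidence in favor of the better model.
#'
#' @param a,b `smc_result` objects for the same observed tree.
#' @return The log Bayes factor (positive favors `a`).
#' @export
log_bayes_factor <- function(a, b) {
  if (!isTRUE(all.equal(a$tree_signature, b$tree_signature))) {
    stop_domain("results are not from the same tree")
  }
  a$log_z - b$log_z
}

# Deliberately misaligned filter (each particle processes the branches in
# its own random topological order): used to demonstrate the variance
# benefit of aligned checkpoints. Internal; not part of the user API.
#' @noRd
run_smc_shuffled <- function(spec, tree, n_particles, seed = NULL,
                             orientation = TRUE) {
  if (!spec$family %in% c("crbd", "tdbd")) {
    stop_domain("the misaligned engine supports the constant-rate and time-dependent families only")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- n_particles
  particles <- init_particles(spec, tree, n)
  k_steps <- 2 * tree$n_tips - 2
  branches <- which(!is.na(tree$parent))
  # each particle processes the branches in its own random order (valid for
  # these families, whose walks carry no per-lineage state)
  orders <- lapply(seq_len(n), function(i) sample(branches))
  log_z <- 0
  lw <- numeric(n)
  for (i in seq_len(k_steps)) {
    for (j in seq_len(n)) {
      node <- orders[[j]][i]
      parent_age <- tree$age[tree$parent[node]]
      r <- step_particle(spec, tree, particles[[j]], node, tree$age[node],
                         parent_age, tree$is_tip[node])
      particles[[j]] <- r$particle
      lw[j] <- r$dlw
    }
    if (all(!is.finite(lw))) {
      stop(sprintf("all particles dead at step %d", i), call. = FALSE)
    }
    log_z <- log_z + log_mean_exp(lw)
    if (i < k_steps) {
      idx <- resample(norm_weights(lw), n, "systematic")
      particles <- particles[idx]
      orders <- orders[idx]
    }
  }
  if (orientation) log_z <- log_z + orientation_correction(tree)
  new_smc_result(spec, tree, log_z, norm_weights(lw),
                 lapply(particles, `[[`, "shared"),
                 data.frame(), n, seed, "smc_shuffled")
}
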
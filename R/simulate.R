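# Forward simulators: complete trees (with extinct and unsampled tips),
# reconstructed trees, stem-lineage summaries, and the deterministic test
# fixtures. Simulation always uses realized parameters (fixed values or one
# prior draw per tree); the event machinery is shared with the hidden-side
# branch simulation of the inference engines.

#' Simulate a complete tree from a crown start
#'
#' Two lineages start at the crown age `t0` and diversify under the model:
#' exponential (or integrated-intensity) waiting times, speciation versus
#' extinction chosen by their relative rates, ClaDS daughters drawing fresh
#' lognormal steps, episodic models switching regimes at rate eta. Each
#' lineage reaching the present is flagged `"extant-sampled"` with
#' probability `rho`, else `"extant-unsampled"`; extinct tips are flagged
#' `"extinct"`.
#'
#' @param spec a `model_spec`; any parameter without a fixed value is drawn
#'   once from its prior.
#' @param t0 crown age (> 0).
#' @param seed optional RNG seed.
#' @param lineage_cap maximum number of lineages before an explosion error.
#' @return A `time_tree` with tip flags.
#' @export
simulate_complete <- function(spec, t0, seed = NULL, lineage_cap = 10000) {
  if (t0 <= 0) stop_domain("t0 must be positive")
  if (!is.null(seed)) set.seed(seed)
  espec <- spec
  espec$delayed <- FALSE
  st <- init_particle_state(espec, t0)
  sh <- st$shared
  parent <- NA_integer_
  age <- t0
  flag <- NA_character_
  n_lin <- 0L
  # stack entries: (parent node id, current age, lineage state)
  stack <- list(list(pnode = 1L, age = t0, lin = st$lin),
                list(pnode = 1L, age = t0, lin = st$lin))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- top$age
    lin <- top$lin
    pnode <- top$pnode
    n_lin <- n_lin + 1L
    if (n_lin > lineage_cap) {
      stop(sprintf("lineage cap (%d) exceeded: the simulated tree explodes", lineage_cap),
           call. = FALSE)
    }
    repeat {
      ev <- hidden_next_event(espec, sh, lin, a)
      sh <- ev$sh
      lin <- ev$lin
      if (ev$type == "present") {
        parent <- c(parent, pnode)
        age <- c(age, 0)
        flag <- c(flag, if (runif(1) < spec$rho) "extant-sampled" else "extant-unsampled")
        break
      }
      a <- a - ev$tau
      if (ev$type == "extinction") {
        parent <- c(parent, pnode)
        age <- c(age, a)
        flag <- c(flag, "extinct")
        break
      }
      if (ev$type == "speciation") {
        parent <- c(parent, pnode)
        age <- c(age, a)
        flag <- c(flag, NA_character_)
        pnode <- length(parent)
        if (spec$model %in% c("ClaDS0", "ClaDS1", "ClaDS2")) {
          s1 <- clads_step(sh); sh <- s1$shared
          s2 <- clads_step(sh); sh <- s2$shared
          stack[[length(stack) + 1L]] <- list(pnode = pnode, age = a,
                                              lin = list(m = lin$m * exp(s1$step)))
          lin <- list(m = lin$m * exp(s2$step))
        } else {
          stack[[length(stack) + 1L]] <- list(pnode = pnode, age = a, lin = lin)
        }
      }
      # switches just update lin and continue
    }
  }
  new_time_tree(parent, age, tip_flag = flag)
}

#' Simulate a reconstructed (observed-style) tree
#'
#' Runs [simulate_complete()], prunes extinct and unsampled tips, and
#' suppresses the resulting unary nodes. With `condition = TRUE` (default)
#' the simulation is rejection-sampled until at least two sampled tips
#' survive, i.e. until there is an observable tree.
#'
#' @inheritParams simulate_complete
#' @param condition rejection-sample until >= 2 sampled tips survive.
#' @param max_tries rejection cap.
#' @return An ultrametric `time_tree` whose crown age is the sampled MRCA age
#'   (at most `t0`).
#' @export
simulate_reconstructed <- function(spec, t0, seed = NULL, condition = TRUE,
                                   lineage_cap = 10000, max_tries = 1e6) {
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    tr <- simulate_complete(spec, t0, lineage_cap = lineage_cap)
    n_sampled <- sum(tr$tip_flag == "extant-sampled", na.rm = TRUE)
    if (n_sampled >= 2) return(prune_to_sampled(tr))
    if (!condition) {
      stop_domain("fewer than 2 sampled tips survived (set condition = TRUE to rejection-sample)")
    }
  }
  stop("rejection cap reached without a surviving tree", call. = FALSE)
}

#' Prune a complete tree to its sampled extant tips
#'
#' Drops extinct and unsampled-extant tips and suppresses unary nodes; the
#' returned tree is rooted at the most recent common ancestor of the sampled
#' tips.
#'
#' @param tree a `time_tree` with tip flags.
#' @return An ultrametric `time_tree`.
#' @export
prune_to_sampled <- function(tree) {
  m <- length(tree$parent)
  keep <- !is.na(tree$tip_flag) & tree$tip_flag == "extant-sampled"
  n_desc <- integer(m)
  # count sampled descendants bottom-up (children were created after parents,
  # so reverse creation order is a valid postorder)
  for (v in rev(seq_len(m))) {
    if (tree$is_tip[v]) {
      n_desc[v] <- as.integer(keep[v])
    }
    p <- tree$parent[v]
    if (!is.na(p)) n_desc[p] <- n_desc[p] + n_desc[v]
  }
  if (n_desc[tree$root] < 2) stop_domain("fewer than 2 sampled tips to keep")
  # descend to the MRCA of the sampled tips
  mrca <- tree$root
  repeat {
    kids <- tree$children[mrca, ]
    live <- kids[n_desc[kids] > 0]
    if (length(live) > 1) break
    mrca <- live
  }
  new_parent <- integer(0)
  new_age <- numeric(0)
  new_label <- character(0)
  build <- function(v, new_p) {
    # skip through unary nodes
    while (!tree$is_tip[v]) {
      kids <- tree$children[v, ]
      live <- kids[n_desc[kids] > 0]
      if (length(live) == 2) break
      v <- live
    }
    new_parent <<- c(new_parent, new_p)
    new_age <<- c(new_age, tree$age[v])
    new_label <<- c(new_label, if (tree$is_tip[v]) tree$tip_label[v] else NA_character_)
    id <- length(new_parent)
    if (!tree$is_tip[v]) {
      kids <- tree$children[v, ]
      for (k in kids[n_desc[kids] > 0]) build(k, id)
    }
    invisible(NULL)
  }
  build(mrca, NA_integer_)
  new_time_tree(new_parent, new_age, tip_label = new_label)
}

#' Summaries of stem-lineage simulations
#'
#' Simulates `reps` independent single-lineage (stem) runs of length `t0`
#' and reports the number of extant and sampled tips of each; used for
#' checking the simulator against birth-process expectations and the
#' analytic extinction probability.
#'
#' @inheritParams simulate_complete
#' @param reps number of replicates.
#' @return data.frame with columns `n_extant`, `n_sampled`.
#' @export
simulate_stem <- function(spec, t0, reps, seed = NULL, lineage_cap = 10000) {
  if (!is.null(seed)) set.seed(seed)
  espec <- spec
  espec$delayed <- FALSE
  n_extant <- integer(reps)
  n_sampled <- integer(reps)
  for (r in seq_len(reps)) {
    st <- init_particle_state(espec, t0)
    sh <- st$shared
    stack <- list(list(age = t0, lin = st$lin))
    ne <- 0L; ns <- 0L; n_lin <- 0L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      a <- top$age
      lin <- top$lin
      n_lin <- n_lin + 1L
      if (n_lin > lineage_cap) {
        stop(sprintf("lineage cap (%d) exceeded", lineage_cap), call. = FALSE)
      }
      repeat {
        ev <- hidden_next_event(espec, sh, lin, a)
        sh <- ev$sh; lin <- ev$lin
        if (ev$type == "present") {
          ne <- ne + 1L
          if (runif(1) < spec$rho) ns <- ns + 1L
          break
        }
        a <- a - ev$tau
        if (ev$type == "extinction") break
        if (ev$type == "speciation") {
          if (spec$model %in% c("ClaDS0", "ClaDS1", "ClaDS2")) {
            s1 <- clads_step(sh); sh <- s1$shared
            s2 <- clads_step(sh); sh <- s2$shared
            stack[[length(stack) + 1L]] <- list(age = a, lin = list(m = lin$m * exp(s1$step)))
            lin <- list(m = lin$m * exp(s2$step))
          } else {
            stack[[length(stack) + 1L]] <- list(age = a, lin = lin)
          }
        }
      }
    }
    n_extant[r] <- ne
    n_sampled[r] <- ns
  }
  data.frame(n_extant = n_extant, n_sampled = n_sampled)
}

#' Monte Carlo extinction probability of a CRBD stem lineage
#'
#' Vectorized simulation of the basic birth-death recursion (exponential
#' waiting time, speciation-vs-extinction coin flip) across many replicates
#' at once: the estimated probability that a single lineage alive at age `t`
#' leaves no sampled descendant. Independent simulation oracle for
#' [extinction_prob_crbd()].
#'
#' @param lambda,mu speciation and extinction rates.
#' @param t stem age.
#' @param rho sampling probability.
#' @param reps number of replicates.
#' @param seed optional RNG seed.
#' @return Estimated extinction (no-sampled-descendant) probability.
#' @export
crbd_extinction_mc <- function(lambda, mu, t, rho = 1, reps = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (t < 0) stop_domain("age must be nonnegative")
  survived <- logical(reps)
  rep_id <- seq_len(reps)
  age <- rep(t, reps)
  p_spec <- lambda / (lambda + mu)
  total <- lambda + mu
  while (length(age)) {
    k <- length(age)
    w <- rexp(k, total)
    reach <- w >= age
    sampled <- reach & (runif(k) < rho)
    if (any(sampled)) survived[unique(rep_id[sampled])] <- TRUE
    keep <- !reach & !survived[rep_id]
    age2 <- age[keep] - w[keep]
    id2 <- rep_id[keep]
    # speciation duplicates the lineage; extinction removes it
    is_spec <- runif(length(age2)) < p_spec
    age <- c(age2[is_spec], age2[is_spec])
    rep_id <- c(id2[is_spec], id2[is_spec])
  }
  1 - mean(survived)
}

# ---------------------------------------------------------------------------

fixture_env <- new.env(parent = emptyenv())

#' Deterministic fixture trees
#'
#' Three small trees used throughout the test suite: the 3-leaf tree
#' `((A:1,B:1):1,C:2);`, and 5- and 20-leaf trees simulated under CRBD with
#' `lambda = 0.2`, `mu = 0.1`, `t0 = 10`. The simulation seed for the 5- and
#' 20-leaf trees is found by a deterministic scan upward from 1 and 2
#' respectively, taking the first seed whose reconstructed tree has the
#' required tip count; the result is bit-stable across runs and sessions.
#'
#' @return Named list of `time_tree` objects: `tree3`, `tree5`, `tree20`.
#' @export
fixture_trees <- function() {
  if (!is.null(fixture_env$trees)) return(fixture_env$trees)
  sp <- model_spec("CRBD", fixed = list(lambda = 0.2, mu = 0.1))
  find_tree <- function(n_tips, seed_start) {
    s <- seed_start
    repeat {
      tr <- simulate_reconstructed(sp, t0 = 10, seed = s)
      if (tr$n_tips == n_tips) return(tr)
      s <- s + 1L
    }
  }
  trees <- list(tree3 = read_newick("((A:1,B:1):1,C:2);"),
                tree5 = find_tree(5L, 1L),
                tree20 = find_tree(20L, 2L))
  fixture_env$trees <- trees
  trees
}
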
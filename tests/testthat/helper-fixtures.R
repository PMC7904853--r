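# Shared fixtures and small helpers for the suite.

tree3 <- function() fixture_trees()$tree3
tree5 <- function() fixture_trees()$tree5
tree20 <- function() fixture_trees()$tree20

# three-standard-error tolerance helper
expect_within_3se <- function(value, target, se, label = NULL) {
  expect_lt(abs(value - target), 3 * se + 1e-12, label = label)
}

# repeated engine runs returning log Z values
rep_logz <- function(engine, spec, tree, n_particles, runs, seed) {
  vapply(seq_len(runs), function(i) {
    r <- switch(engine,
      smc = run_smc(spec, tree, n_particles, seed = seed + i),
      apf = run_apf(spec, tree, n_particles, seed = seed + i),
      is = run_importance_sampling(spec, tree, n_particles, seed = seed + i))
    r$log_z
  }, numeric(1))
}
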
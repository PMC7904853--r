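# divsmc

Bayesian comparison of biological diversification models on time-calibrated
phylogenies by sequential Monte Carlo.

Evolutionary biologists ask whether a clade's speciation rate was constant,
slowed through time, or shifted across lineages — and extinction likewise.
`divsmc` implements nine birth-death diversification models over an observed
ultrametric tree of extant species:

| family | models | rate structure |
|---|---|---|
| constant rate | CRB (Yule), CRBD | constant λ (and μ) |
| time dependent | TDB, TDBD | λ(t) = λ₀·e^{z(t₀−t)}, constant turnover μ/λ |
| cladogenetic shifts | ClaDS0/1/2 | each daughter draws log λᵢ ~ N(log(α·λₐ), σ²) |
| episodic shifts | LSBDS, BAMM | Poisson(η) switch points redraw the rates |

Instead of per-model likelihood formulas, every model is a *generative
program*: an SMC particle simulates the hidden side of the process along
the observed tree (hidden speciations whose descendants must leave no
sampled tip, extinction non-events, rate switches), accumulating the
probability of what is observed. The mean particle weight is an unbiased
estimate of the marginal likelihood Z = p(τ_obs | model), so differences of
log Ẑ are log Bayes factors (≥ 5 log units: strong evidence). Three engines
are provided:

* `run_smc` — bootstrap particle filter with resampling **aligned** at the
  observed speciation events, so all particles are compared on the same
  portion of the tree;
* `run_apf` — the **alive particle filter**: re-proposes until N particles
  with nonzero weight are collected and corrects Ẑ with the unbiased
  (N−1)/(A−1) attempts factor; collapses bitwise to multinomial SMC when no
  particle dies;
* `run_importance_sampling` — closed-form likelihood weighting for
  CRB/CRBD/TDB/TDBD.

**Delayed sampling** keeps conjugate parameters as gamma /
normal-inverse-gamma beliefs inside each particle instead of sampled values
(gamma-Poisson and normal-inverse-gamma marginalization), which demonstrably
reduces the variance of log Ẑ and yields posteriors as analytic mixtures.
The `analytics` functions (`extinction_prob_crbd`, `crbd_loglik`,
`tdbd_loglik`) provide the closed-form and ODE-quadrature oracles used to
verify the filters, and `simulate_complete` / `simulate_reconstructed` are
exact forward simulators for all nine models.

## Worked example

```r
library(divsmc)
tr <- fixture_trees()$tree5          # 5-tip CRBD fixture, crown age 10

# 1. verification mode: fixed parameters against the analytic likelihood
an <- crbd_loglik(tr, crbd_params(0.2, 0.1))
lz <- replicate(100, run_smc(model_spec("CRBD",
        fixed = list(lambda = 0.2, mu = 0.1)), tr, 1000)$log_z)
round(c(analytic = an, filter_mean = mean(lz), filter_sd = sd(lz)), 4)
#>    analytic filter_mean   filter_sd
#>     -8.2456     -8.2425      0.1137

# 2. model comparison under Gamma(1,1) priors
cmp <- div_compare(list(CRB = model_spec("CRB"), CRBD = model_spec("CRBD")),
                   tr, engine = "apf", n_particles = 500, runs = 5, seed = 1)
cmp$summary
#>   model mean_log_z   sd_log_z
#> 1   CRB  -9.034113 0.00000000
#> 2  CRBD -11.106984 0.06472496
```

The first block shows the core verification property: the filter's mean
log Ẑ reproduces the analytic log-likelihood (here within 0.004, with a
per-run spread of 0.11 at 1000 particles). The second block estimates
marginal likelihoods under priors: the pure-birth program on a fully
sampled tree is deterministic given the delayed rate belief, hence its zero
spread, and it beats the birth-death model by ~2.1 log units — real but
below the 5-unit strong-evidence bar, so these five tips do not firmly
distinguish the models.

A thin command-line tool wraps the same functions:

```sh
exec/divsmc simulate --model CRBD --t0 10 --seed 1 --out sim/tree
exec/divsmc infer   --tree sim/tree.nwk --model ClaDS2 --engine apf \
                    --particles 1000 --runs 5 --seed 1 --out runs/
exec/divsmc compare --tree sim/tree.nwk --models CRB,CRBD,ClaDS2 --out cmp/
exec/divsmc verify  --seed 1 --out verify/
```

## Scope

Observed trees must be binary, ultrametric, with branch lengths in time
units; incomplete sampling is handled by the ρ-sampling model (each extant
tip sampled independently with probability ρ). Serially sampled tips,
fossilization, and trait-dependent rates are out of scope. See the methods
vignette (`vignettes/diversification-smc.Rmd`) for the model and estimator
details, numerical choices, and the design of the recovery study.
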
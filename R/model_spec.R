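# Model specification: which diversification model, its priors, the
# tip-sampling fraction rho, and engine-relevant flags.
#
# The nine models and their parameters:
#   CRB     constant-rate birth (Yule): lambda
#   CRBD    constant-rate birth-death: lambda, mu
#   TDB     time-dependent birth: lambda0, z          (lambda(t) decays/grows)
#   TDBD    time-dependent birth-death: lambda0, z, eps (turnover mu/lambda
#           held constant through time)
#   ClaDS0  cladogenetic rate shifts, no extinction: lambda0, log alpha, sigma2
#   ClaDS1  ClaDS with constant mu
#   ClaDS2  ClaDS with constant turnover: the lineage multiplier scales an
#           independent mu0 alongside lambda0, so mu_i / lambda_i = mu0 /
#           lambda0 on every lineage and both rates stay conjugate
#   LSBDS   episodic CRBD: Poisson(eta) switches redraw lambda (mu constant
#           by default; both redrawn with `lsbds_redraw_mu`)
#   BAMM    episodic TDBD with constant-mu regimes: switches redraw
#           (lambda0, mu, z) and reset the decay clock.

MODEL_IDS <- c("CRB", "CRBD", "TDB", "TDBD",
               "ClaDS0", "ClaDS1", "ClaDS2", "LSBDS", "BAMM")

#' @noRd
model_params_needed <- function(model) {
  switch(model,
    CRB    = "lambda",
    CRBD   = c("lambda", "mu"),
    TDB    = c("lambda", "z"),
    TDBD   = c("lambda", "z", "eps"),
    ClaDS0 = c("lambda", "log_alpha", "sigma2"),
    ClaDS1 = c("lambda", "log_alpha", "sigma2", "mu"),
    ClaDS2 = c("lambda", "log_alpha", "sigma2", "mu"),
    LSBDS  = c("lambda", "mu", "eta"),
    BAMM   = c("lambda", "mu", "z", "eta"))
}

#' Default prior hyperparameters
#'
#' Gamma(shape 1, rate 1) on the rates lambda, mu and eta; Normal(0, 0.1) on
#' the time-dependence parameter z; normal-inverse-gamma (m = 0, nu = 1,
#' a = 1, b = 0.2) on the ClaDS (log alpha, sigma^2); Uniform(0, 1) on the
#' turnover eps. All of these are placeholders a user is expected to adapt
#' to the time units of the tree at hand.
#'
#' @return Nested list of hyperparameters.
#' @export
default_priors <- function() {
  list(lambda = list(shape = 1, rate = 1),
       mu     = list(shape = 1, rate = 1),
       eta    = list(shape = 1, rate = 1),
       z      = list(mean = 0, sd = 0.1),
       clads  = list(m = 0, nu = 1, a = 1, b = 0.2),
       eps    = list(min = 0, max = 1))
}

#' Construct a diversification model specification
#'
#' @param model one of `"CRB"`, `"CRBD"`, `"TDB"`, `"TDBD"`, `"ClaDS0"`,
#'   `"ClaDS1"`, `"ClaDS2"`, `"LSBDS"`, `"BAMM"`.
#' @param rho tip sampling probability in (0, 1].
#' @param priors prior hyperparameters; missing entries filled from
#'   [default_priors()].
#' @param fixed named list of fixed parameter values overriding the priors
#'   (likelihood-verification mode). Allowed names depend on the model:
#'   `lambda`, `mu`, `eps`, `z`, `log_alpha`, `sigma2`, `eta`.
#' @param delayed use delayed (conjugate) sampling where available; with
#'   `FALSE` every parameter is realized from its prior at particle
#'   initialization (eager mode).
#' @param survivorship apply the survivorship-bias correction.
#' @param lsbds_redraw_mu LSBDS variant: also redraw mu at switch points.
#' @param bamm_reset_clock reset the exponential decay reference age at BAMM
#'   switch points (default); `FALSE` keeps the crown-age anchor.
#' @param hidden_cap maximum number of hidden side-lineage segments processed
#'   per subtree before the particle is declared dead.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(model, rho = 1, priors = list(), fixed = list(),
                       delayed = TRUE, survivorship = FALSE,
                       lsbds_redraw_mu = FALSE, bamm_reset_clock = TRUE,
                       hidden_cap = 10000) {
  model <- match.arg(model, MODEL_IDS)
  if (rho <= 0 || rho > 1) stop_domain("rho must be in (0, 1]")
  pr <- utils::modifyList(default_priors(), priors)
  needed <- model_params_needed(model)
  extra <- setdiff(names(fixed), needed)
  if (length(extra)) {
    stop_domain("fixed parameter(s) %s not used by model %s",
                paste(extra, collapse = ", "), model)
  }
  family <- switch(model, CRB = , CRBD = "crbd", TDB = , TDBD = "tdbd",
                   ClaDS0 = , ClaDS1 = , ClaDS2 = "clads",
                   LSBDS = "lsbds", BAMM = "bamm")
  structure(list(model = model, family = family, rho = rho, priors = pr,
                 fixed = fixed,
                 delayed = isTRUE(delayed), survivorship = isTRUE(survivorship),
                 lsbds_redraw_mu = isTRUE(lsbds_redraw_mu),
                 bamm_reset_clock = isTRUE(bamm_reset_clock),
                 hidden_cap = hidden_cap),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %s (rho = %g, %s)\n", x$model, x$rho,
              if (x$delayed) "delayed" else "eager"))
  if (length(x$fixed)) {
    cat("  fixed:", paste(sprintf("%s = %g", names(x$fixed),
                                  unlist(x$fixed)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a model specification from a YAML config file
#'
#' Recognized keys: `model`, `rho`, `priors.{lambda,mu,eta}.{shape,rate}`,
#' `priors.z.{mean,sd}`, `priors.clads.{m,nu,a,b}`, `priors.eps.{min,max}`,
#' `fixed.<param>`, and the flags `delayed`, `survivorship`,
#' `lsbds_redraw_mu`, `bamm_reset_clock`, `hidden_cap`.
#'
#' @param path path to a YAML file.
#' @return A `model_spec`; remaining top-level keys are attached as the
#'   `"run"` attribute (engine, particles, runs, seed, tree, out ...).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop_domain("config must name a model")
  spec <- model_spec(
    model = cfg$model,
    rho = if (is.null(cfg$rho)) 1 else cfg$rho,
    priors = if (is.null(cfg$priors)) list() else cfg$priors,
    fixed = if (is.null(cfg$fixed)) list() else cfg$fixed,
    delayed = if (is.null(cfg$delayed)) TRUE else cfg$delayed,
    survivorship = if (is.null(cfg$survivorship)) FALSE else cfg$survivorship,
    lsbds_redraw_mu = if (is.null(cfg$lsbds_redraw_mu)) FALSE else cfg$lsbds_redraw_mu,
    bamm_reset_clock = if (is.null(cfg$bamm_reset_clock)) TRUE else cfg$bamm_reset_clock,
    hidden_cap = if (is.null(cfg$hidden_cap)) 10000 else cfg$hidden_cap)
  run_keys <- setdiff(names(cfg), c("model", "rho", "priors", "fixed", "delayed",
                                    "survivorship", "lsbds_redraw_mu",
                                    "bamm_reset_clock", "hidden_cap"))
  attr(spec, "run") <- cfg[run_keys]
  spec
}
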
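# Shared fixtures. The long simulations are memoised so that the
# acceptance tests and the unit tests that inspect the same protocol reuse
# one run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Converged orthogonal-input ramp at the anticipation protocol's published
# parameters (tau = 9 ms, tau_eff = 600 ms, eta = 50, 500 synapses).
fig2_run <- function() {
  memo("fig2", {
    cfg <- ramp_config(input = "orthogonal", n_syn = 500, n_periods = 500,
                       plasticity = plasticity_params(alpha = 0.985,
                                                      eta = 50, tau = 9))
    run_ramp_experiment(cfg)
  })
}

# Frozen 2 Hz trains, 1000 afferents, elevated learning rate; correlation
# with the fixed-point prediction tracked per trial.
t2_run <- function(seed = 11) {
  memo(paste0("t2_", seed), {
    cfg <- ramp_config(input = "frozen_poisson", n_syn = 1000, rate = 0.002,
                       n_periods = 100, seed = seed,
                       plasticity = plasticity_params(alpha = 0.985,
                                                      eta = 50, tau = 9),
                       track_correlation = TRUE)
    run_ramp_experiment(cfg)
  })
}

# Small random irreducible chain with full-rank PSP matrix and admissible
# (lam, gamma) for the convergence condition lam * alpha < 1 - gamma.
random_environment <- function(n, alpha, seed) {
  set.seed(seed)
  T <- matrix(stats::rexp(n * n), n, n) + 0.05
  T <- T / rowSums(T)
  B <- diag(n) + 0.3 * matrix(stats::runif(n * n), n, n)
  gamma <- stats::runif(1, 0.02, 0.2)
  lam <- stats::runif(1, 0.1, (1 - gamma) / alpha * 0.9)
  markov_environment(T, B, r_I = stats::runif(n, 0, 0.05),
                     lam = lam, gamma = gamma)
}

rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
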
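test_that("discounting operator matches its series and row-sum identity", {
  env <- example_markov_environment()
  for (alpha in c(0.5, 0.9)) {
    A <- discount_operator(env, alpha)
    expect_equal(A, discount_operator(env, alpha, method = "series"),
                 tolerance = 1e-11)
    expect_equal(rowSums(A), rep(alpha / (1 - env$gamma), env$n_states),
                 tolerance = 1e-10)
  }
  # gamma = 0 keeps only the t = 0 term
  env0 <- markov_environment(env$T, env$B, env$r_I, env$lam, gamma = 0)
  expect_equal(discount_operator(env0, 0.7), 0.7 * diag(3))
  # two-state symmetric chain, worked by hand via the geometric series
  Tsym <- matrix(0.5, 2, 2)
  envs <- markov_environment(Tsym, diag(2), c(1, 0), lam = 0.5, gamma = 0.5)
  expect_equal(discount_operator(envs, 1),
               matrix(c(1.5, 0.5, 0.5, 1.5), 2), tolerance = 1e-12)
})

test_that("Markov fixed point solves the discounted self-consistency", {
  # fully clamped dendrite (lam = 0): no bootstrapping, r_V = A r_I
  Tc <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  env <- markov_environment(Tc, diag(2), c(1, 0), lam = 0, gamma = 0.5)
  rv <- markov_fixed_point(env, 1)
  expect_equal(rv, c(4 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(rv, as.numeric(discount_operator(env, 1) %*% env$r_I))
  # solve and series routes agree on random chains
  for (seed in 1:4) {
    env <- random_environment(5, alpha = 0.9, seed = seed)
    expect_equal(markov_fixed_point(env, 0.9),
                 markov_fixed_point(env, 0.9, method = "series"),
                 tolerance = 1e-9)
  }
  env <- example_markov_environment()
  expect_error(markov_fixed_point(env, 1.2), "convergence condition")
})

test_that("discounting operator contracts in the pi-weighted norm", {
  for (seed in 1:5) {
    env <- random_environment(6, alpha = 0.9, seed = seed + 50)
    A <- discount_operator(env, 0.9) * (1 - env$gamma) / 0.9  # unit row sums
    nrm <- function(z) sqrt(sum(env$pi * z^2))
    for (r in 1:5) {
      z <- stats::rnorm(6)
      expect_lte(nrm(as.numeric(A %*% z)), nrm(z) + 1e-12)
    }
  }
})

test_that("gamma_eff grows monotonically towards 1 at the critical alpha", {
  env <- example_markov_environment()
  lam <- env$lam[1]
  a_crit <- (1 - env$gamma) / lam
  alphas <- seq(0.1, 0.999, length.out = 40) * a_crit
  ge <- vapply(alphas, function(a) effective_discount(env, a), 0)
  expect_true(all(diff(ge) > 0))
  expect_true(all(ge < 1))
  expect_gt(ge[40], 0.97)
})

test_that("mean weight ODE descends its Lyapunov function to the fixed point", {
  for (seed in 1:3) {
    env <- random_environment(4, alpha = 0.85, seed = seed + 10)
    ode <- mean_ode_trajectory(env, alpha = 0.85, eta = 1, n_steps = 8000)
    expect_true(all(diff(ode$L) <= 1e-12))
    expect_equal(ode$r_V, markov_fixed_point(env, 0.85), tolerance = 1e-6)
  }
  # no somatic input: the learned code decays to zero
  env <- example_markov_environment()
  env0 <- markov_environment(env$T, env$B, r_I = c(0, 0, 0), env$lam[1],
                             env$gamma)
  ode <- mean_ode_trajectory(env0, 0.9, eta = 1, w0 = c(1, -2, 0.5),
                             n_steps = 8000)
  expect_equal(ode$r_V, c(0, 0, 0), tolerance = 1e-8)
})

test_that("affine transfer shifts the fixed point by the offset term", {
  # phi(u) = u + c amounts to replacing r_I by r_I - c in the linear solve
  env <- example_markov_environment()
  alpha <- 0.9
  cshift <- 0.01
  A <- discount_operator(env, alpha)
  lam <- env$lam[1]
  rv_shift <- solve(diag(3) - lam * A, A %*% (env$r_I - cshift))
  env2 <- markov_environment(env$T, env$B, env$r_I - cshift, lam, env$gamma)
  expect_equal(as.numeric(rv_shift), markov_fixed_point(env2, alpha),
               tolerance = 1e-12)
})

test_that("value function matches the learned code when gamma_TD = gamma_eff", {
  env <- example_markov_environment()
  alpha <- 0.9
  td <- td_params(gamma_TD = effective_discount(env, alpha))
  expect_equal(value_function(env, alpha, td), markov_fixed_point(env, alpha),
               tolerance = 1e-9)
  # one-state chain: geometric series in closed form
  env1 <- markov_environment(matrix(1), matrix(1), r_I = 0.04, lam = 0.5,
                             gamma = 0.3)
  td1 <- td_params(gamma_TD = 0.6)
  expect_equal(value_function(env1, 0.8, td1),
               (0.8 / (1 - 0.8 * 0.5)) * 0.04 / (1 - 0.6))
  expect_equal(value_function(env, alpha, td) * 0,
               value_function(markov_environment(env$T, env$B, c(0, 0, 0),
                                                 env$lam[1], env$gamma),
                              alpha, td))
})

test_that("TD(lambda) sampling converges to the value function", {
  env <- example_markov_environment()
  alpha <- 0.9
  gte <- effective_discount(env, alpha)
  td <- td_params(gamma_TD = gte, lambda_TD = 0.5, eta = 0.02)
  res <- td_lambda_learn(env, alpha, td, seed = 4, n_steps = 40000)
  V <- value_function(env, alpha, td)
  expect_lt(max(abs(res$v_hat - V)) / max(V), 0.05)
  # initialised at the exact value function, the delta error is zero on
  # average
  w_star <- solve(env$B, V)
  res0 <- td_lambda_learn(env, alpha, td_params(gte, 0.5, eta = 0),
                          seed = 7, n_steps = 10000, w0 = w_star)
  expect_lt(abs(res0$mean_delta),
            3 * res0$sd_delta / sqrt(10000))
})

test_that("the rule's trace equals the TD eligibility trace when matched", {
  # lambda_TD gamma_TD = gamma makes the two recursions identical
  env <- example_markov_environment()
  gte <- effective_discount(env, 0.9)
  lam_td <- env$gamma / gte
  set.seed(12)
  x <- procode:::sample_chain(env, 200)
  tr_rule <- numeric(3); tr_td <- numeric(3)
  for (t in seq_along(x)) {
    tr_rule <- env$gamma * tr_rule + env$B[x[t], ]
    tr_td <- lam_td * gte * tr_td + env$B[x[t], ]
  }
  expect_equal(tr_rule, tr_td, tolerance = 1e-12)
})

test_that("prospective rule and dendritic TD(1) move along one trajectory", {
  env <- example_markov_environment()
  alpha <- 0.9
  w0 <- c(0.1, 0.05, 0.12)
  e1 <- td1_equivalence_check(env, alpha, eta = 1e-3, seed = 2,
                              n_steps = 2000, w0 = w0)
  e2 <- td1_equivalence_check(env, alpha, eta = 5e-4, seed = 2,
                              n_steps = 2000, w0 = w0)
  # raw discrepancy is the O(eta) telescoping boundary: halves with eta
  expect_equal(e1$max_discrepancy / e2$max_discrepancy, 2, tolerance = 0.05)
  # subtracting the analytic boundary leaves a higher-order residual
  expect_lt(e1$max_residual, 0.15 * e1$max_discrepancy)
  e0 <- td1_equivalence_check(env, alpha, eta = 0, seed = 2, n_steps = 500)
  expect_identical(e0$max_discrepancy, 0)
})

test_that("environment construction validates its stochastic structure", {
  expect_error(markov_environment(matrix(c(0.5, 0.6, 0.6, 0.4), 2),
                                  diag(2), c(0, 0), 1, 0.5), "sum to 1")
  env <- example_markov_environment()
  expect_equal(as.numeric(env$pi %*% env$T), env$pi, tolerance = 1e-12)
  expect_true(all(env$pi > 0))
  expect_error(markov_environment(env$T, env$B, env$r_I, 1, 0.5,
                                  pi = c(0.5, 0.3, 0.2)), "not stationary")
})
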
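test_that("spike-response kernel is causal, unimodal and normalised", {
  p <- neuron_params()
  expect_equal(psp_kernel(-1, p), 0)
  t <- seq(0, 200, 0.001)
  k <- psp_kernel(t, p)
  expect_true(all(k >= 0))
  # quadrature (trapezoid) over [0, 200] captures the unit integral
  expect_equal(sum((k[-1] + k[-length(k)]) / 2) * 0.001, 1,
               tolerance = 1e-6)
  # single interior maximum at tau_m tau_s log(tau_m/tau_s)/(tau_m - tau_s)
  t_peak <- p$tau_m * p$tau_s * log(p$tau_m / p$tau_s) /
    (p$tau_m - p$tau_s)
  expect_equal(t[which.max(k)], t_peak, tolerance = 1e-2)
  expect_equal(t_peak, 5.493, tolerance = 1e-3)
  d <- diff(k[t >= 0 & t <= 60])
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)  # one sign change
})

test_that("dendritic potential is the weighted kernel sum and is linear", {
  p <- neuron_params()
  spk <- spike_train_set(list(c(50), numeric(0), c(10, 30)), 200)
  tgrid <- seq(0, 199.9, 0.1)
  v1 <- dendritic_potential(c(1, 0, 0), spk, 0.1, p)
  expect_equal(v1, psp_kernel(tgrid - 50, p))
  v <- dendritic_potential(c(0.5, 2, -1), spk, 0.1, p)
  manual <- 0.5 * psp_kernel(tgrid - 50, p) -
    (psp_kernel(tgrid - 10, p) + psp_kernel(tgrid - 30, p))
  expect_equal(v, manual)
  # linearity in the weight vector
  w <- c(0.3, 1.2, -0.4)
  expect_equal(dendritic_potential(2 * w, spk, 0.1, p),
               2 * dendritic_potential(w, spk, 0.1, p))
  expect_equal(dendritic_potential(c(0, 0, 0), spk, 0.1, p),
               rep(0, 2000))
  expect_error(dendritic_potential(c(1, 2), spk, 0.1, p), "length")
})

test_that("periodic spike trains wrap the convolution across the boundary", {
  p <- neuron_params()
  spk <- spike_train_set(list(c(195)), 200, periodic = TRUE)
  v <- dendritic_potential(1, spk, 0.1, p)
  # a spike late in the period shapes the early part of the next period
  expect_gt(v[51], 0.9 * psp_kernel(10, p))  # t = 5 ms, 10 ms after spike
  v_open <- dendritic_potential(1, spike_train_set(list(c(195)), 200), 0.1, p)
  expect_equal(v_open[51], 0)
})

test_that("somatic integration follows the conductance-based leaky ODE", {
  p <- neuron_params()
  n <- 5000
  # free decay towards rest with time constant C/(g_L + g_D) ~ 0.526 ms
  # (fine dt so the Euler trajectory tracks the exact exponential)
  fine <- conductance_schedule(numeric(2000), numeric(2000), 0.01)
  U <- integrate_soma(p, rep(0, 2000), fine, 0.01, U0 = 1)
  tau_C <- 1000 * p$C / (p$g_L + p$g_D)
  expect_equal(tau_C, 1 / 1.9, tolerance = 1e-12)
  t <- (seq_len(2000) - 1) * 0.01
  expect_equal(U[1:400], exp(-t[1:400] / tau_C), tolerance = 0.02)
  silent <- conductance_schedule(numeric(n), numeric(n), 0.1)
  # constant dendritic drive: fixed point g_D v / (g_L + g_D)
  U <- integrate_soma(p, rep(0.5, n), silent, 0.1)
  expect_equal(U[n], p$g_D * 0.5 / (p$g_L + p$g_D), tolerance = 1e-10)
  expect_equal(U[n], (1800 / 1900) * 0.5, tolerance = 1e-12)
  # constant conductances settle onto the steady-state decomposition
  sched <- conductance_schedule(rep(10, n), rep(2, n), 0.1)
  U <- integrate_soma(p, rep(0.3, n), sched, 0.1)
  ss <- steady_state_decomposition(0.3, 10, 2, p)
  expect_equal(U[n], ss$U_approx, tolerance = 1e-10)
  expect_error(integrate_soma(p, rep(0, 10),
                              conductance_schedule(rep(1e5, 10), 0, 0.1),
                              0.1),
               "unstable")
})

test_that("steady-state decomposition reproduces the nudging algebra", {
  p <- neuron_params()
  ss <- steady_state_decomposition(0, 0, 0, p)
  expect_equal(ss$lambda, 1)
  expect_equal(ss$U_approx, 0)
  ss <- steady_state_decomposition(0, 15, 0, p)
  expect_equal(ss$lambda, 1900 / 1915)
  expect_equal(ss$U_star, 70 / 1915)
  # lambda always in (0, 1]
  g <- matrix(stats::runif(200, 0, 500), 100, 2)
  lam <- steady_state_decomposition(0, g[, 1], g[, 2], p)$lambda
  expect_true(all(lam > 0 & lam <= 1))
})

test_that("integration agrees with the steady state for slow conductances", {
  # piecewise-constant conductances held much longer than C/g_tot
  p <- neuron_params()
  dt <- 0.1
  seg <- rep(c(0, 10, 25, 5), each = 500)  # 50 ms per level
  sched <- conductance_schedule(seg, 0.2 * seg, dt)
  V_w <- rep(0.4, length(seg))
  U <- integrate_soma(p, V_w, sched, dt)
  ss <- steady_state_decomposition(V_w, sched$g_E, sched$g_I, p)
  # compare after each transient (skip 10 * C/g_tot ~ 5 ms per segment)
  keep <- rep(c(rep(FALSE, 100), rep(TRUE, 400)), 4)
  expect_lt(max(abs(U[keep] - ss$U_approx[keep]) / abs(ss$U_approx[keep])),
            0.02)
})

test_that("transfer function clips at rest and saturation", {
  p <- neuron_params()
  expect_equal(firing_rate(0.5, p), 0.03)
  expect_equal(firing_rate(-0.2, p), 0)
  expect_equal(firing_rate(2, p), 0.06)
  U <- seq(-2, 3, 0.01)
  r <- firing_rate(U, p)
  expect_true(all(r >= 0 & r <= p$phi_max))
})

test_that("Bernoulli spike sampling is calibrated and reproducible", {
  rate <- rep(0.06, 1e6)
  s1 <- sample_spikes(rate, 0.1, seed = 42)
  s2 <- sample_spikes(rate, 0.1, seed = 42)
  expect_identical(s1, s2)
  # binomial mean 6000, sd sqrt(n p (1-p)) ~ 77.4
  expect_lt(abs(length(s1) - 6000), 5 * sqrt(1e6 * 0.006 * 0.994))
  expect_identical(sample_spikes(rep(0, 1000), 0.1, seed = 1), numeric(0))
  expect_error(sample_spikes(rep(20, 10), 0.1), "exceed")
})

test_that("compiled simulator matches the plain-R reference on one period", {
  p <- neuron_params()
  pl <- plasticity_params(alpha = 0.9, eta = 2, tau = 9)
  set.seed(3)
  spk <- frozen_poisson(5, 0.02, 200, 0.1, seed = 8)
  n <- 2000
  sched <- conductance_schedule(rep(c(0, 12), each = n / 2), 0, 0.1)
  res <- procode:::sim_segment(spk, sched, procode:::new_state(5),
                               p, pl, 0.1, learn = TRUE, record = TRUE)
  # reference: explicit-kernel dendritic potential with zero weights is 0,
  # so replay the coupled recursion step by step in R
  w <- numeric(5); Am <- numeric(5); As <- numeric(5); Pt <- numeric(5)
  dm <- exp(-0.1 / p$tau_m); ds <- exp(-0.1 / p$tau_s)
  kc <- 1 / (p$tau_m - p$tau_s)
  aT <- exp(-0.1 / pl$tau)
  bins <- lapply(spk$spike_times, function(t) floor(t / 0.1))
  U <- 0; Cms <- 1000 * p$C
  phiU_ref <- numeric(n)
  for (k in 0:(n - 1)) {
    Am <- Am * dm; As <- As * ds
    psp <- kc * (Am - As)
    vw <- sum(w * psp)
    gE <- sched$g_E[k + 1]
    U <- U + 0.1 / Cms * (-p$g_L * U + p$g_D * (vw - U) + gE * (p$E_E - U))
    vstar <- p$g_D / (p$g_L + p$g_D) * vw
    phiU <- firing_rate(U, p); phiV <- firing_rate(vstar, p)
    phiU_ref[k + 1] <- phiU
    Pt <- aT * Pt + (1 - aT) * psp
    w <- w + 0.1 * pl$eta * (pl$alpha * phiU * Pt - phiV * psp)
    for (i in 1:5) Am[i] <- Am[i] + sum(bins[[i]] == k)
    for (i in 1:5) As[i] <- As[i] + sum(bins[[i]] == k)
  }
  expect_equal(res$phiU, phiU_ref, tolerance = 1e-12)
  expect_equal(res$w, w, tolerance = 1e-12)
})

test_that("single-bin weight_step matches the rule arithmetic", {
  p <- neuron_params()
  st <- synapse_state(weights = 0, psp = 0.3, psp_tilde = 0.4)
  pl <- plasticity_params(alpha = 0.9, eta = 1, tau = 9)
  st2 <- weight_step(st, U = 0.5, V_star = 0.2, pl, p, dt = 0.1)
  expect_equal(st2$weights, 7.2e-4)
})
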
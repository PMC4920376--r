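test_that("orthogonal pattern spaces one spike per synapse evenly", {
  spk <- orthogonal_pattern(4, 2000, 0.1)
  expect_equal(unlist(spk$spike_times), c(0, 500, 1000, 1500))
  spk <- orthogonal_pattern(500, 2000, 0.1)
  expect_true(all(lengths(spk$spike_times) == 1))
  gaps <- diff(sort(unlist(spk$spike_times)))
  expect_equal(unique(gaps), 4)
  # inter-spike gap across channels stays within the PSP support
  expect_lte(2000 / 500, 25)
  expect_error(orthogonal_pattern(10, 1, 0.5))
})

test_that("frozen Poisson trains are reproducible with Poisson statistics", {
  a <- frozen_poisson(500, 0.02, 2000, 0.1, seed = 3)
  b <- frozen_poisson(500, 0.02, 2000, 0.1, seed = 3)
  expect_identical(a, b)
  counts <- lengths(a$spike_times)
  # mean count 40 per channel; 5 sigma band for the mean of 500 channels
  expect_lt(abs(mean(counts) - 40), 5 * sqrt(40 / 500))
  expect_true(all(lengths(frozen_poisson(20, 0, 2000, 0.1,
                                         seed = 1)$spike_times) == 0))
  expect_true(a$periodic)
})

test_that("inhomogeneous Poisson sampling follows its rate profile", {
  n_bins <- 5000
  prof <- matrix(rep(c(0.002, 0.04), each = n_bins / 2), n_bins, 1)
  counts_lo <- counts_hi <- numeric(200)
  for (r in 1:200) {
    s <- inhomogeneous_poisson(prof, 0.1, seed = 1000 + r)
    tt <- s$spike_times[[1]]
    counts_lo[r] <- sum(tt < 250)
    counts_hi[r] <- sum(tt >= 250)
  }
  # expected 0.5 and 10 spikes per trial in the two halves
  expect_lt(abs(mean(counts_lo) - 0.5), 5 * sqrt(0.5 / 200))
  expect_lt(abs(mean(counts_hi) - 10), 5 * sqrt(10 / 200))
  expect_identical(inhomogeneous_poisson(prof, 0.1, seed = 5),
                   inhomogeneous_poisson(prof, 0.1, seed = 5))
})

test_that("template trajectories have the OU stationary statistics", {
  p <- ou_params()
  tpl <- stm_templates(200, p, duration = 60000, dt = 1, seed = 2)
  expect_named(tpl, c("A1", "A2"))
  # stationary mean 0 across neurons; stationary sd sigma1/sqrt(2 theta1)
  sd_stat <- p$sigma1 / sqrt(2 * p$theta1)
  m <- mean(tpl$A1)
  expect_lt(abs(m), 5 * sd_stat / sqrt(200))  # conservative (correlated in t)
  expect_equal(stats::sd(as.numeric(tpl$A2[1, ])), sd_stat, tolerance = 0.25)
  # empirical autocorrelation time ~ 1/theta1 within 20%, estimated from
  # the lag-1 autocorrelation (long-lag sample ACFs are strongly biased)
  tau_hat <- sapply(1:200, function(i) {
    r1 <- stats::acf(tpl$A1[, i], lag.max = 1, plot = FALSE)$acf[2]
    -1 / log(r1)
  })
  expect_equal(mean(tau_hat), 1000, tolerance = 0.2)
})

test_that("trial rates approach the template only inside the trial window", {
  p <- ou_params()
  tpl <- stm_templates(150, p, duration = 2000, dt = 1, seed = 6)
  same1 <- stm_traces(150, p, "A1", c(0, 2000), dt = 1, seed = 21,
                      templates = tpl)
  same2 <- stm_traces(150, p, "A1", c(0, 2000), dt = 1, seed = 22,
                      templates = tpl)
  diff2 <- stm_traces(150, p, "A2", c(0, 2000), dt = 1, seed = 23,
                      templates = tpl)
  per_neuron_cor <- function(a, b)
    sapply(seq_len(ncol(a)), function(i) stats::cor(a[, i], b[, i]))
  c_same <- mean(per_neuron_cor(same1$rates, same2$rates))
  c_diff <- mean(per_neuron_cor(same1$rates, diff2$rates))
  expect_gt(c_same, c_diff + 0.2)  # shared template binds same-label trials
  # outside the stimulus window the rates are template-independent noise
  out1 <- stm_traces(150, p, "A1", c(-2000, 0), dt = 1, seed = 31,
                     templates = tpl)
  out2 <- stm_traces(150, p, "A1", c(-2000, 0), dt = 1, seed = 32,
                     templates = tpl)
  expect_lt(abs(mean(per_neuron_cor(out1$rates, out2$rates))), 0.15)
})

test_that("sinusoidal somatic drive has the stated value, mean and sign", {
  sched <- fig5_conductance(2000, 0.1)
  expect_equal(sched$g_E[1], 6)
  expect_equal(mean(sched$g_E), 6, tolerance = 1e-6)
  expect_true(all(sched$g_E >= 0))
  expect_true(all(sched$g_I == 0))
})

test_that("sequential stimulation partitions groups one at a time", {
  st <- sequential_stimulation(4, 50, pulse_ms = 100, g_E_on = 20, dt = 0.1)
  expect_equal(st$span, 400)
  expect_equal(length(st$group), 200)
  active <- rowSums(st$gE > 0)
  expect_true(all(active == 1))  # exactly one group driven per bin
  expect_equal(colSums(st$gE > 0), rep(1000, 4))
  rec <- sequential_stimulation(4, 50, recall = TRUE, recall_ms = 20,
                                dt = 0.1)
  expect_true(all(rec$gE[, 2:4] == 0))
  expect_equal(sum(rec$gE[, 1] > 0), 200)
})

test_that("probabilistic event thinning is Bernoulli with probability p", {
  base <- conductance_schedule(rep(15, 100), 0, 0.1)
  all_on <- probabilistic_event(base, 1, 50, seed = 1)
  expect_true(all(vapply(all_on, function(s) max(s$g_E) == 15, TRUE)))
  all_off <- probabilistic_event(base, 0, 50, seed = 1)
  expect_true(all(vapply(all_off, function(s) max(s$g_E) == 0, TRUE)))
  many <- probabilistic_event(base, 0.5, 1000, seed = 8)
  n_on <- sum(vapply(many, function(s) max(s$g_E) > 0, TRUE))
  expect_lt(abs(n_on - 500), 5 * sqrt(1000 * 0.25))
  expect_identical(probabilistic_event(base, 0.5, 20, seed = 3),
                   probabilistic_event(base, 0.5, 20, seed = 3))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(frozen_poisson(10, 0.02, 500, 0.1, seed = 7))
  invisible(stm_templates(5, duration = 100, dt = 1, seed = 7))
  expect_identical(stats::runif(1), before)
})
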
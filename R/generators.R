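#' Parameters of the short-term-memory rate process
#'
#' Ornstein-Uhlenbeck parameters for the stochastic process that stands in
#' for a recurrent short-term memory network: per-neuron template rate
#' trajectories are drawn once from a mean-zero OU process (inverse
#' correlation time `theta1`, noise scale `sigma1`), and per-trial rates
#' relax towards a template-dependent mean (inverse time constant `theta2`)
#' with a noise variance that drops from `sigma_out^2` to `sigma_in^2` at
#' stimulus onset (stimulus onset quenches variability).
#'
#' @param theta1 inverse correlation time of the templates (1/ms).
#' @param sigma1 template noise scale.
#' @param theta2 inverse relaxation time of the per-trial rates (1/ms).
#' @param sigma_in,sigma_out trial noise s.d. inside / outside the stimulus
#'   window (variances 0.1 and 1 by default).
#' @return An object of class `ou_params`.
#' @export
ou_params <- function(theta1 = 1 / 1000, sigma1 = 1, theta2 = 1 / 100,
                      sigma_in = sqrt(0.1), sigma_out = 1) {
  stopifnot(theta1 > 0, sigma1 > 0, theta2 > 0, sigma_in > 0, sigma_out > 0)
  structure(list(theta1 = theta1, sigma1 = sigma1, theta2 = theta2,
                 sigma_in = sigma_in, sigma_out = sigma_out),
            class = "ou_params")
}

#' Orthogonal single-spike input pattern
#'
#' Deterministic pattern in which synapse `i` fires exactly once per period,
#' at `(i - 1) * period / n_syn`: evenly spaced, non-overlapping single
#' spikes covering the whole period.
#'
#' @param n_syn number of synapses.
#' @param period trial period (ms).
#' @param dt grid step (ms); `n_syn` must not exceed `period / dt`.
#' @return a periodic [spike_train_set()].
#' @export
orthogonal_pattern <- function(n_syn, period = 2000, dt = 0.1) {
  stopifnot(n_syn >= 1, n_syn <= period / dt)
  times <- (seq_len(n_syn) - 1) * period / n_syn
  spike_train_set(as.list(times), duration = period, periodic = TRUE)
}

#' Frozen Poisson spike trains
#'
#' One homogeneous Poisson draw per channel that is then replayed
#' identically every period.
#'
#' @param n number of channels.
#' @param rate firing rate (kHz).
#' @param period trial period (ms).
#' @param dt grid step (ms).
#' @param seed integer seed; the same seed reproduces the same trains.
#' @return a periodic [spike_train_set()].
#' @export
frozen_poisson <- function(n, rate, period = 2000, dt = 0.1, seed = 1) {
  n_bins <- round(period / dt)
  trains <- with_seed(seed, {
    lapply(seq_len(n), function(i)
      sample_spikes(rep(rate, n_bins), dt))
  })
  spike_train_set(trains, duration = period, periodic = TRUE)
}

#' Inhomogeneous Poisson spike trains from rate profiles
#'
#' Fresh Bernoulli sampling from per-channel rate profiles; used for
#' trial-to-trial stochastic spiking with repeating rates.
#'
#' @param rate_profiles matrix of rates (kHz), bins x channels.
#' @param dt grid step (ms).
#' @param seed optional integer seed.
#' @param periodic mark the resulting set as periodic.
#' @return a [spike_train_set()].
#' @export
inhomogeneous_poisson <- function(rate_profiles, dt = 0.1, seed = NULL,
                                  periodic = TRUE) {
  rate_profiles <- as.matrix(rate_profiles)
  duration <- nrow(rate_profiles) * dt
  trains <- with_seed(seed, {
    lapply(seq_len(ncol(rate_profiles)), function(i)
      sample_spikes(rate_profiles[, i], dt))
  })
  spike_train_set(trains, duration = duration, periodic = periodic)
}

# Euler-Maruyama paths of dr = -theta (r - mu) dt + sigma dW, vectorised
# over columns (neurons). mu: n_bins vector or n_bins x n matrix; sigma:
# length-n_bins vector; r0: length-n vector. Returns an n_bins x n matrix.
ou_path <- function(n_bins, dt, theta, mu, sigma, r0) {
  n <- length(r0)
  mu_mat <- is.matrix(mu)
  if (!mu_mat) mu <- rep_len(mu, n_bins)
  sigma <- rep_len(sigma, n_bins)
  r <- matrix(NA_real_, n_bins, n)
  x <- r0
  sq <- sqrt(dt)
  for (k in seq_len(n_bins)) {
    m <- if (mu_mat) mu[k, ] else mu[k]
    x <- x + theta * (m - x) * dt + sigma[k] * sq * stats::rnorm(n)
    r[k, ] <- x
  }
  r
}

#' Template rate trajectories for the short-term memory
#'
#' Draws, once per neuron and stimulus label, a template trajectory from the
#' mean-zero OU process, started from its stationary distribution.
#'
#' @param n_neurons number of STM neurons.
#' @param params an [ou_params()].
#' @param duration template duration (ms).
#' @param dt grid step (ms).
#' @param seed integer seed.
#' @param labels stimulus labels.
#' @return list of template matrices (bins x neurons), one per label.
#' @export
stm_templates <- function(n_neurons, params = ou_params(), duration = 3000,
                          dt = 0.1, seed = 1, labels = c("A1", "A2")) {
  n_bins <- round(duration / dt)
  sd_stat <- params$sigma1 / sqrt(2 * params$theta1)
  with_seed(seed, {
    out <- lapply(labels, function(lab)
      ou_path(n_bins, dt, params$theta1, 0, params$sigma1,
              stats::rnorm(n_neurons, 0, sd_stat)))
    names(out) <- labels
    out
  })
}

#' Per-trial short-term-memory rates and spikes
#'
#' Generates one trial of STM activity: per-neuron rates relax towards the
#' template of the presented stimulus with mean
#' `mu_s(t) = (1 - sigma(t)) r_s(t) - sigma(t)/2` and noise s.d. `sigma(t)`
#' that drops from `sigma_out` to `sigma_in` inside the stimulus window
#' `[0, template duration)` (times are relative to stimulus onset; the
#' window can start before 0 to model pre-trial activity). Spikes are
#' sampled from an inhomogeneous Bernoulli process at rate `phi(r_i(t))`.
#'
#' @param n_neurons number of STM neurons.
#' @param params an [ou_params()].
#' @param stimulus label selecting the template.
#' @param trial_window `c(start, end)` (ms) relative to stimulus onset.
#' @param dt grid step (ms).
#' @param seed optional integer seed.
#' @param templates templates from [stm_templates()]; generated (seeded by
#'   `seed`) when missing.
#' @param neuron a [neuron_params()] supplying the transfer function.
#' @param r0 initial rates (defaults to a stationary out-of-trial draw).
#' @return list with the rate matrix (bins x neurons), the spikes as a
#'   [spike_train_set()] (times shifted so the window starts at 0), and the
#'   final rates (for chaining segments).
#' @export
stm_traces <- function(n_neurons, params = ou_params(), stimulus = "A1",
                       trial_window = c(0, 3000), dt = 0.1, seed = NULL,
                       templates = NULL, neuron = neuron_params(),
                       r0 = NULL) {
  if (is.null(templates))
    templates <- stm_templates(n_neurons, params, trial_window[2], dt,
                               seed = if (is.null(seed)) 1 else seed)
  tpl <- templates[[stimulus]]
  stopifnot(ncol(tpl) == n_neurons)
  n_bins <- round((trial_window[2] - trial_window[1]) / dt)
  t_rel <- trial_window[1] + (seq_len(n_bins) - 1) * dt
  tpl_dur <- nrow(tpl) * dt
  inside <- t_rel >= 0 & t_rel < tpl_dur
  sig <- ifelse(inside, params$sigma_in, params$sigma_out)
  idx_tpl <- pmin(pmax(floor(t_rel / dt) + 1, 1), nrow(tpl))
  with_seed(seed, {
    mu <- (1 - sig) * tpl[idx_tpl, , drop = FALSE] - sig / 2
    mu[!inside, ] <- -params$sigma_out / 2  # template-independent outside
    start <- if (is.null(r0))
      stats::rnorm(n_neurons, mu[1, ],
                   params$sigma_out / sqrt(2 * params$theta2))
    else r0
    rates <- ou_path(n_bins, dt, params$theta2, mu, sig, start)
    spikes <- inhomogeneous_poisson(firing_rate(rates, neuron), dt,
                                    periodic = FALSE)
    list(rates = rates, spikes = spikes, r_end = rates[n_bins, ])
  })
}

#' Sinusoidal somatic conductance of the time-series protocol
#'
#' `g_E(t) = 6 (1 - sin(wt) sin(2wt) cos(4wt))` nS with
#' `w = 2 pi / period`; `g_I = 0`. Non-negative with period mean 6 nS.
#'
#' @param period period (ms).
#' @param dt grid step (ms).
#' @return a [conductance_schedule()].
#' @export
fig5_conductance <- function(period = 2000, dt = 0.1) {
  t <- (seq_len(round(period / dt)) - 1) * dt
  w <- 2 * pi / period
  gE <- 6 * (1 - sin(w * t) * sin(2 * w * t) * cos(4 * w * t))
  conductance_schedule(gE, 0, dt)
}

#' Sequential group stimulation schedule
#'
#' Somatic drive for the recurrent-network protocol: the population is
#' partitioned into `n_groups` groups of `group_size` neurons; during one
#' training sweep group `k` receives `g_E_on` for `pulse_ms`, one group at a
#' time, so a sweep spans `n_groups * pulse_ms` (plus an optional gap).
#' Recall mode drives only group 1, briefly.
#'
#' @param n_groups number of groups.
#' @param group_size neurons per group.
#' @param pulse_ms pulse duration per group (ms).
#' @param g_E_on drive amplitude (nS).
#' @param dt grid step (ms).
#' @param gap_ms silent gap appended after the sweep (ms).
#' @param recall if `TRUE`, return a recall schedule: only group 1 is
#'   stimulated, for `recall_ms`, followed by silence for the rest of
#'   the sweep span.
#' @param recall_ms duration of the recall pulse (ms).
#' @return list with the per-group conductance matrix `gE` (bins x groups),
#'   the 1-based group assignment vector `group` (length
#'   `n_groups * group_size`), `dt` and the sweep span (ms).
#' @export
sequential_stimulation <- function(n_groups, group_size, pulse_ms = 100,
                                   g_E_on = 20, dt = 0.1, gap_ms = 0,
                                   recall = FALSE, recall_ms = 20) {
  span <- n_groups * pulse_ms + gap_ms
  n_bins <- round(span / dt)
  gE <- matrix(0, n_bins, n_groups)
  if (recall) {
    gE[seq_len(round(recall_ms / dt)), 1] <- g_E_on
  } else {
    for (k in seq_len(n_groups)) {
      i0 <- round((k - 1) * pulse_ms / dt) + 1
      i1 <- round(k * pulse_ms / dt)
      gE[i0:i1, k] <- g_E_on
    }
  }
  list(gE = gE, group = rep(seq_len(n_groups), each = group_size),
       dt = dt, span = span)
}

#' Bernoulli thinning of a somatic event schedule
#'
#' Each trial independently keeps the somatic pulse with probability
#' `p_event` or silences it entirely, modelling a training event that occurs
#' only in a fraction of trials.
#'
#' @param base_schedule a [conductance_schedule()].
#' @param p_event event probability in `[0, 1]`.
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @return list of `n_trials` conductance schedules (shared copies, no
#'   duplication in memory).
#' @export
probabilistic_event <- function(base_schedule, p_event, n_trials, seed = 1) {
  stopifnot(p_event >= 0, p_event <= 1)
  zero <- conductance_schedule(numeric(base_schedule$n_bins),
                               numeric(base_schedule$n_bins),
                               base_schedule$dt)
  keep <- with_seed(seed, stats::runif(n_trials) < p_event)
  lapply(keep, function(k) if (k) base_schedule else zero)
}
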
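#' Configuration of an anticipatory-ramp experiment
#'
#' Training protocol: a fixed (or per-trial resampled) pattern of
#' presynaptic spikes repeats every `period` ms, and the soma receives an
#' excitatory pulse `g_E_on` during `event_window`. Starting from zero
#' weights, the plasticity rule grows a firing-rate ramp that anticipates
#' the pulse with the effective discount time constant
#' `tau / (1 - lam alpha)`.
#'
#' @param input one of `"orthogonal"`, `"frozen_poisson"`,
#'   `"inhomogeneous_poisson"`.
#' @param n_syn number of synapses.
#' @param period trial period (ms).
#' @param rate presynaptic rate (kHz) for the Poisson inputs.
#' @param rate_profiles optional bins x channels rate matrix for
#'   `"inhomogeneous_poisson"`; defaults to smoothed frozen-Poisson-like
#'   random profiles with mean `rate`.
#' @param event_window `c(on, off)` of the somatic pulse (ms).
#' @param g_E_on pulse amplitude (nS).
#' @param g_I_factor `g_I = g_I_factor * g_E` (the matched-window control
#'   uses 4).
#' @param p_event probability that a training period contains the pulse.
#' @param n_periods training periods.
#' @param neuron,plasticity parameter objects.
#' @param dt grid step (ms).
#' @param seed integer seed for generators.
#' @param pre_event_window interval (ms) on which learned and theoretical
#'   rates are compared.
#' @param fit_window interval (ms) for the exponential ramp fit.
#' @param amp_window interval (ms) over which the ramp amplitude (mean
#'   dendritic rate) is measured.
#' @param track_correlation if `TRUE`, record the correlation with the
#'   theoretical fixed point after every training period.
#' @return list of class `ramp_config`.
#' @export
ramp_config <- function(input = c("orthogonal", "frozen_poisson",
                                  "inhomogeneous_poisson"),
                        n_syn = 500, period = 2000, rate = 0.02,
                        rate_profiles = NULL,
                        event_window = c(1800, 2000), g_E_on = 15,
                        g_I_factor = 0, p_event = 1, n_periods = 500,
                        neuron = neuron_params(),
                        plasticity = plasticity_params(alpha = 0.985,
                                                       eta = 50, tau = 9),
                        dt = 0.1, seed = 1,
                        pre_event_window = c(0, 1800),
                        fit_window = c(600, 1800),
                        amp_window = c(1500, 1800),
                        track_correlation = FALSE) {
  structure(list(input = match.arg(input), n_syn = n_syn, period = period,
                 rate = rate, rate_profiles = rate_profiles,
                 event_window = event_window, g_E_on = g_E_on,
                 g_I_factor = g_I_factor, p_event = p_event,
                 n_periods = n_periods, neuron = neuron,
                 plasticity = plasticity, dt = dt, seed = seed,
                 pre_event_window = pre_event_window,
                 fit_window = fit_window, amp_window = amp_window,
                 track_correlation = track_correlation),
            class = "ramp_config")
}

# Somatic pulse schedule of a ramp protocol.
ramp_schedule <- function(cfg) {
  n_bins <- round(cfg$period / cfg$dt)
  t <- (seq_len(n_bins) - 1) * cfg$dt
  gE <- ifelse(t >= cfg$event_window[1] & t < cfg$event_window[2],
               cfg$g_E_on, 0)
  conductance_schedule(gE, cfg$g_I_factor * gE, cfg$dt)
}

# Theoretical stationary dendritic rate for a ramp protocol: the periodic
# fixed point of the somatic rate phi(U*), scaled by the event probability
# (the fixed point is linear in the mean somatic rate).
ramp_theory <- function(cfg) {
  sched <- ramp_schedule(cfg)
  ss <- steady_state_decomposition(0, sched$g_E, sched$g_I, cfg$neuron)
  phiU <- firing_rate(ss$U_star, cfg$neuron)
  cfg$p_event * periodic_fixed_point(phiU, lam = 1,
                                     alpha = cfg$plasticity$alpha,
                                     tau = cfg$plasticity$tau, dt = cfg$dt)
}

window_bins <- function(window, dt, n_bins) {
  i0 <- max(1, round(window[1] / dt) + 1)
  i1 <- min(n_bins, round(window[2] / dt))
  i0:i1
}

#' Run an anticipatory-ramp experiment
#'
#' Trains a neuron under a [ramp_config()] protocol, probes it with the
#' somatic input silenced, and compares the learned dendritic rate to the
#' theoretical fixed point on the pre-event interval.
#'
#' Reported metrics: Pearson `correlation` and relative RMS error
#' (`rms_rel`, RMS of the difference over RMS of the theory) between learned
#' and theoretical rate on `pre_event_window`; `amplitude` (mean learned
#' dendritic rate over `amp_window`); `tau_fit` from
#' [fit_ramp_time_constant()] over `fit_window` (NA if the fit degenerates).
#' With `track_correlation`, `corr_history` holds the per-period correlation
#' and `first_learned` the first period at which it reaches 0.9.
#'
#' @param cfg a [ramp_config()].
#' @return object of class `ramp_experiment`.
#' @export
run_ramp_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "ramp_config"))
  n_bins <- round(cfg$period / cfg$dt)
  sched_base <- ramp_schedule(cfg)
  # the fixed-point curve needs tau > 0 and lam*alpha < 1; the
  # matched-window control (tau = 0) runs without a theory reference
  theory <- tryCatch(ramp_theory(cfg), error = function(e) NULL)
  pre <- window_bins(cfg$pre_event_window, cfg$dt, n_bins)

  input <- switch(cfg$input,
    orthogonal = orthogonal_pattern(cfg$n_syn, cfg$period, cfg$dt),
    frozen_poisson = frozen_poisson(cfg$n_syn, cfg$rate, cfg$period, cfg$dt,
                                    seed = cfg$seed),
    inhomogeneous_poisson = {
      profiles <- cfg$rate_profiles
      if (is.null(profiles))
        profiles <- smooth_rate_profiles(cfg$n_syn, cfg$rate, cfg$period,
                                         cfg$dt, seed = cfg$seed)
      local({
        p <- profiles
        function(i) inhomogeneous_poisson(p, cfg$dt,
                                          seed = cfg$seed + 7919L * i)
      })
    })

  schedule <- if (cfg$p_event < 1)
    probabilistic_event(sched_base, cfg$p_event, cfg$n_periods,
                        seed = cfg$seed + 104729L)
  else sched_base

  metric_fn <- if (cfg$track_correlation && !is.null(theory))
    function(res, i) suppressWarnings(stats::cor(res$phiV[pre], theory[pre]))
  else NULL

  fit <- train_neuron(input, schedule, cfg$neuron, cfg$plasticity,
                      cfg$n_periods, cfg$dt, metric_fn = metric_fn)

  probe_input <- if (is.function(input)) input(cfg$n_periods + 1) else input
  probe <- probe_neuron(fit$state, probe_input, cfg$neuron, cfg$plasticity,
                        cfg$dt)
  phiV <- probe$phiV
  if (!is.null(theory)) {
    corr <- suppressWarnings(stats::cor(phiV[pre], theory[pre]))
    rms_abs <- sqrt(mean((phiV[pre] - theory[pre])^2))
    rms_rel <- rms_abs / sqrt(mean(theory[pre]^2))
    nrmse_range <- rms_abs / max(theory)
  } else {
    corr <- rms_rel <- nrmse_range <- NA_real_
  }
  amp_bins <- window_bins(cfg$amp_window, cfg$dt, n_bins)
  tau_fit <- tryCatch(
    fit_ramp_time_constant(phiV, cfg$dt, event_time = cfg$event_window[1],
                           fit_window = cfg$fit_window),
    error = function(e) NA_real_)
  corr_history <- if (cfg$track_correlation) unlist(fit$metrics) else NULL
  first_learned <- if (!is.null(corr_history)) {
    idx <- which(corr_history >= 0.9)
    if (length(idx)) idx[1] else NA_integer_
  } else NULL
  structure(list(config = cfg, weights = fit$weights, probe = probe,
                 training_trace = fit$trace, theory = theory,
                 metrics = list(correlation = corr, rms_rel = rms_rel,
                                nrmse_range = nrmse_range,
                                amplitude = mean(phiV[amp_bins]),
                                tau_fit = tau_fit),
                 corr_history = corr_history,
                 first_learned = first_learned),
            class = "ramp_experiment")
}

#' @export
print.ramp_experiment <- function(x, ...) {
  m <- x$metrics
  cat("Anticipatory-ramp experiment (", x$config$input, " input, ",
      x$config$n_periods, " periods)\n", sep = "")
  cat(sprintf("  correlation with fixed-point theory: %.4f\n", m$correlation))
  cat(sprintf("  relative RMS error (pre-event):      %.4f\n", m$rms_rel))
  cat(sprintf("  ramp amplitude: %.4g kHz; fitted tau: %.4g ms\n",
              m$amplitude, m$tau_fit))
  if (!is.null(x$first_learned))
    cat(sprintf("  correlation first reached 0.9 at period %s\n",
                x$first_learned))
  invisible(x)
}

# Smooth periodic random rate profiles with mean `rate`: white noise
# circularly convolved with an exponential kernel (correlation time
# tau_smooth), standardised and rectified; rich temporal structure for the
# stochastic-spiking protocols.
smooth_rate_profiles <- function(n_syn, rate, period, dt, seed = 1,
                                 tau_smooth = 50) {
  n_bins <- round(period / dt)
  kern <- exp(-(0:(n_bins - 1)) * dt / tau_smooth)
  kern_hat <- stats::fft(kern / sum(kern))
  with_seed(seed, {
    m <- matrix(stats::rnorm(n_bins * n_syn), n_bins, n_syn)
    for (j in seq_len(n_syn)) {
      x <- Re(stats::fft(stats::fft(m[, j]) * kern_hat,
                         inverse = TRUE)) / n_bins
      m[, j] <- x / stats::sd(x)
    }
    pmax(rate * (1 + 1.5 * m), 0)  # mean ~rate, clipped at rest
  })
}

#' Fit the time constant of an exponential ramp
#'
#' Least-squares fit of `a * exp((t - event_time) / tau)` to a rate trace on
#' `fit_window`, with the amplitude profiled out and `tau` found by 1-D
#' optimisation.
#'
#' @param rate rate trace on the grid (kHz).
#' @param dt grid step (ms).
#' @param event_time time (ms) towards which the ramp rises.
#' @param fit_window `c(from, to)` (ms) used for the fit.
#' @param tau_range search interval for `tau` (ms).
#' @return fitted `tau` (ms).
#' @export
fit_ramp_time_constant <- function(rate, dt, event_time,
                                   fit_window = c(event_time - 1200,
                                                  event_time),
                                   tau_range = c(10, 5000)) {
  idx <- window_bins(fit_window, dt, length(rate))
  r <- rate[idx]
  t <- (idx - 1) * dt - event_time
  if (all(r <= 0) || stats::sd(r) == 0)
    stop("degenerate (flat) trace: cannot fit a ramp time constant")
  rss <- function(tau) {
    k <- exp(t / tau)
    a <- sum(r * k) / sum(k * k)
    sum((r - a * k)^2)
  }
  stats::optimize(rss, tau_range)$minimum
}

#' Lag of maximal circular cross-correlation
#'
#' Circular cross-correlation between a learned rate curve and the rate
#' determined by the somatic input alone, both periodic with the same
#' length. The returned lag (ms, in `(-period/2, period/2]`) is positive
#' when the learned rate leads (anticipates) the somatic rate.
#'
#' @param rate_U learned firing-rate curve (one period).
#' @param rate_Ustar somatic-input rate curve (same grid).
#' @param dt grid step (ms).
#' @return lag (ms) at the correlation peak.
#' @export
advancement_peak <- function(rate_U, rate_Ustar, dt = 0.1) {
  n <- length(rate_U)
  stopifnot(length(rate_Ustar) == n)
  a <- rate_U - mean(rate_U)
  b <- rate_Ustar - mean(rate_Ustar)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance input: advancement undefined")
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b),
                      inverse = TRUE)) / n
  lag <- which.max(cc) - 1
  if (lag > n / 2) lag <- lag - n
  lag * dt
}

#' Time-series advancement experiment
#'
#' Trains a neuron on frozen Poisson dendritic input against the sinusoidal
#' somatic conductance of [fig5_conductance()] and measures the advancement
#' of the learned firing rate relative to the rate determined by the
#' somatic input alone, via [advancement_peak()] on the final training
#' period.
#'
#' @param n_syn,rate,period,n_periods,dt,seed protocol scale.
#' @param neuron,plasticity parameter objects.
#' @param g_I_factor balancing inhibition `g_I = g_I_factor * g_E`; the
#'   matched-window control (`tau = 0`, `alpha = 1`, the rule in which the
#'   dendrite predicts current somatic firing) uses 4, which keeps the
#'   dendritic fixed point finite under weak nudging.
#' @return list with the advancement (ms), the two rate curves and the
#'   final weights.
#' @export
run_advancement_experiment <- function(n_syn = 500, rate = 0.01,
                                       period = 2000, n_periods = 200,
                                       neuron = neuron_params(),
                                       plasticity = plasticity_params(
                                         alpha = 0.9, eta = 0.5, tau = 5),
                                       dt = 0.1, seed = 1, g_I_factor = 0) {
  input <- frozen_poisson(n_syn, rate, period, dt, seed = seed)
  sched <- fig5_conductance(period, dt)
  if (g_I_factor > 0)
    sched <- conductance_schedule(sched$g_E, g_I_factor * sched$g_E, dt)
  fit <- train_neuron(input, sched, neuron, plasticity, n_periods, dt)
  ss <- steady_state_decomposition(0, sched$g_E, sched$g_I, neuron)
  rate_Ustar <- firing_rate(ss$U_star, neuron)
  adv <- advancement_peak(fit$trace$phiU, rate_Ustar, dt)
  list(advancement = adv, rate_U = fit$trace$phiU, rate_Ustar = rate_Ustar,
       weights = fit$weights)
}

#' Delayed paired-associate experiment
#'
#' Readout neurons learn to anticipate their target-specific somatic drive
#' from the spatio-temporal memory trace left by the sample stimulus in a
#' population of short-term-memory (STM) neurons. Samples A1/A2 are drawn
#' with equal probability; the associated target arrives `target_window`
#' after stimulus onset and drives each readout's soma with a
#' target-specific conductance. After training, probe trials (no somatic
#' input, learning frozen) measure the mean firing rate in the late delay
#' period per sample identity.
#'
#' @param n_stm number of STM neurons.
#' @param n_trials training trials.
#' @param trial_len length (ms) of the low-noise (in-trial) window.
#' @param target_window `c(on, off)` (ms) of the target drive.
#' @param delay_window `c(from, to)` (ms) over which the probe rate is
#'   averaged (late delay).
#' @param g_E_target per-readout drive (nS) for each sample: a matrix with
#'   one row per readout and columns A1, A2.
#' @param iti_range intertrial interval range (ms), drawn uniformly.
#' @param n_probe probe trials per sample identity.
#' @param ou an [ou_params()].
#' @param neuron,plasticity parameter objects.
#' @param dt grid step (ms).
#' @param seed integer seed.
#' @return object of class `paired_associate`, with the per-readout,
#'   per-sample mean delay rates in `amplitudes`.
#' @export
run_paired_associate <- function(n_stm = 200, n_trials = 60,
                                 trial_len = 3000,
                                 target_window = c(1500, 1700),
                                 delay_window = c(1300, 1500),
                                 g_E_target = rbind(n1 = c(5, 0),
                                                    n2 = c(0, 5),
                                                    n3 = c(5, 2.5)),
                                 iti_range = c(3000, 10000),
                                 n_probe = 8,
                                 ou = ou_params(),
                                 neuron = neuron_params(),
                                 plasticity = plasticity_params(
                                   alpha = 0.985, eta = 0.5, tau = 9),
                                 dt = 0.1, seed = 1) {
  labels <- c("A1", "A2")
  n_read <- nrow(g_E_target)
  n_bins_trial <- round(trial_len / dt)
  tw <- window_bins(target_window, dt, n_bins_trial)
  dw <- window_bins(delay_window, dt, n_bins_trial)

  with_seed(seed, {
    templates <- stm_templates(n_stm, ou, trial_len, dt,
                               seed = sample.int(.Machine$integer.max, 1))
    states <- lapply(seq_len(n_read), function(i) new_state(n_stm))
    r_cur <- NULL
    zero_trial <- conductance_schedule(numeric(n_bins_trial),
                                       numeric(n_bins_trial), dt)
    for (tr in seq_len(n_trials)) {
      iti <- stats::runif(1, iti_range[1], iti_range[2])
      seg_iti <- stm_traces(n_stm, ou, labels[1], c(-iti, 0), dt,
                            templates = templates, neuron = neuron,
                            r0 = r_cur)
      lab <- sample(labels, 1)
      seg_trial <- stm_traces(n_stm, ou, lab, c(0, trial_len), dt,
                              templates = templates, neuron = neuron,
                              r0 = seg_iti$r_end)
      r_cur <- seg_trial$r_end
      n_bins_iti <- round(iti / dt)
      zero_iti <- conductance_schedule(numeric(n_bins_iti),
                                       numeric(n_bins_iti), dt)
      for (i in seq_len(n_read)) {
        res <- sim_segment(seg_iti$spikes, zero_iti, states[[i]], neuron,
                           plasticity, dt, learn = TRUE)
        states[[i]] <- res[c("w", "Am", "As", "Pt", "U")]
        gE <- numeric(n_bins_trial)
        gE[tw] <- g_E_target[i, match(lab, labels)]
        res <- sim_segment(seg_trial$spikes,
                           conductance_schedule(gE, 0, dt), states[[i]],
                           neuron, plasticity, dt, learn = TRUE)
        states[[i]] <- res[c("w", "Am", "As", "Pt", "U")]
      }
    }
    # probe: fresh trials per sample, learning frozen, soma silent
    amplitudes <- matrix(0, n_read, 2,
                         dimnames = list(rownames(g_E_target), labels))
    for (lab_i in 1:2) {
      for (pr in seq_len(n_probe)) {
        seg <- stm_traces(n_stm, ou, labels[lab_i], c(0, trial_len), dt,
                          templates = templates, neuron = neuron)
        for (i in seq_len(n_read)) {
          res <- sim_segment(seg$spikes, zero_trial, states[[i]], neuron,
                             plasticity, dt, learn = FALSE, record = TRUE)
          amplitudes[i, lab_i] <- amplitudes[i, lab_i] +
            mean(res$phiU[dw]) / n_probe
        }
      }
    }
    structure(list(amplitudes = amplitudes, weights = lapply(states, `[[`,
                                                             "w"),
                   g_E_target = g_E_target, n_trials = n_trials),
              class = "paired_associate")
  })
}

#' @export
print.paired_associate <- function(x, ...) {
  cat("Delayed paired-associate experiment (", x$n_trials, " trials)\n",
      sep = "")
  cat("Mean late-delay firing rate (kHz) per readout and sample:\n")
  print(round(x$amplitudes, 6))
  invisible(x)
}

#' Recurrent-network sequence replay experiment
#'
#' An all-to-all recurrent network (no autapses) of `n_groups * group_size`
#' neurons receives slow sequential somatic stimulation; the prospective
#' plasticity rule, active throughout, strengthens connections from each
#' group to its successors. After training, a brief stimulation of group 1
#' evokes an autonomous replay of the whole sequence at a compressed
#' timescale.
#'
#' @param n_groups,group_size population structure.
#' @param pulse_ms training pulse duration per group (ms).
#' @param g_E_on drive amplitude (nS).
#' @param n_repeats training sweeps.
#' @param recall_ms duration of the recall pulse to group 1 (ms).
#' @param g_E_recall amplitude (nS) of the recall pulse; a strong brief
#'   stimulation that makes group 1 fire a synchronous burst, which the
#'   learned forward connections relay through the remaining groups.
#' @param n_recalls number of recall pulses; the evoked group rates are
#'   averaged across pulses before peak extraction, since a single replay
#'   of the later groups carries only a handful of spikes. Learning is
#'   frozen during these probe pulses (a repeated strong burst would
#'   otherwise imprint direct group-1 connections onto every responsive
#'   neuron and corrupt the replay timing being measured).
#' @param recall_span observation window after recall onset (ms).
#' @param settle_ms silent interval between training and recall (ms).
#' @param smooth_ms width of the boxcar used to smooth group rates before
#'   peak extraction (ms).
#' @param neuron,plasticity parameter objects.
#' @param dt grid step (ms).
#' @param seed integer seed.
#' @return object of class `recurrent_replay` with metrics
#'   `order_concordance` (Kendall correlation of group peak times with the
#'   training order; 1 = perfect order) and `compression` (training span
#'   between first and last group peak divided by the replay span; > 1
#'   means faster-than-training replay). Metrics are `NA` when the network
#'   produces no replay activity.
#' @export
run_recurrent_replay <- function(n_groups = 4, group_size = 25,
                                 pulse_ms = 100, g_E_on = 20,
                                 n_repeats = 300, recall_ms = 20,
                                 g_E_recall = 500, n_recalls = 8,
                                 recall_span = 600, settle_ms = 300,
                                 smooth_ms = 15,
                                 neuron = neuron_params(),
                                 plasticity = plasticity_params(
                                   alpha = 0.95, eta = 3, tau = 9),
                                 dt = 0.1, seed = 1) {
  n <- n_groups * group_size
  train <- sequential_stimulation(n_groups, group_size, pulse_ms, g_E_on, dt)
  recall <- sequential_stimulation(n_groups, group_size, pulse_ms, g_E_on,
                                   dt, recall = TRUE, recall_ms = recall_ms)
  group0 <- as.integer(train$group - 1L)
  sim <- function(gE, st, learn, record) {
    cpp_sim_recurrent(nrow(gE), group0, gE, st$W, st$Am, st$As, st$Pt,
                      st$U, dt, neuron$C, neuron$g_L, neuron$g_D,
                      neuron$E_E, neuron$E_I, neuron$phi_max, neuron$tau_m,
                      neuron$tau_s, plasticity$eta, plasticity$alpha,
                      plasticity$tau, learn, record)
  }
  with_seed(seed, {
    st <- list(W = matrix(0, n, n), Am = numeric(n), As = numeric(n),
               Pt = numeric(n), U = numeric(n))
    for (r in seq_len(n_repeats)) {
      res <- sim(train$gE, st, learn = TRUE, record = FALSE)
      st <- res[c("W", "Am", "As", "Pt", "U")]
    }
    # settle, then probe replay; weights are frozen for the probe pulses
    n_settle <- round(settle_ms / dt)
    n_rec <- round(recall_span / dt)
    gE_rec <- matrix(0, n_rec, n_groups)
    n_pulse <- min(round(recall_ms / dt), n_rec)
    gE_rec[seq_len(n_pulse), 1] <- g_E_recall
    rate <- matrix(0, n_rec, n)
    spikes <- NULL
    for (r in seq_len(n_recalls)) {
      res <- sim(matrix(0, n_settle, n_groups), st, learn = FALSE,
                 record = FALSE)
      st <- res[c("W", "Am", "As", "Pt", "U")]
      res <- sim(gE_rec, st, learn = FALSE, record = TRUE)
      st <- res[c("W", "Am", "As", "Pt", "U")]
      rate <- rate + res$rate / n_recalls  # bins x neurons, phi(U)
      if (r == 1)
        spikes <- data.frame(time = res$spike_bin * dt,
                             neuron = res$spike_neuron)
    }
    grp_rate <- sapply(seq_len(n_groups), function(g)
      rowMeans(rate[, train$group == g, drop = FALSE]))
    k <- max(1, round(smooth_ms / dt))
    sm <- apply(grp_rate, 2, function(x)
      stats::filter(x, rep(1 / k, k), sides = 2))
    sm[is.na(sm)] <- 0
    peaks <- apply(sm, 2, which.max)
    peak_rates <- apply(sm, 2, max)
    active <- peak_rates > 1e-4  # kHz; groups with measurable replay
    if (!all(active)) {
      concord <- NA_real_
      compression <- NA_real_
    } else {
      concord <- stats::cor(peaks, seq_len(n_groups), method = "kendall")
      replay_span <- (peaks[n_groups] - peaks[1]) * dt
      train_span <- (n_groups - 1) * pulse_ms
      compression <- if (replay_span > 0) train_span / replay_span
        else NA_real_
    }
    structure(list(order_concordance = concord, compression = compression,
                   peak_times = (peaks - 1) * dt, peak_rates = peak_rates,
                   group_rates = grp_rate, weights = st$W,
                   spikes = spikes,
                   n_groups = n_groups, group_size = group_size),
              class = "recurrent_replay")
  })
}

#' @export
print.recurrent_replay <- function(x, ...) {
  cat(sprintf("Recurrent replay: %d groups x %d neurons\n",
              x$n_groups, x$group_size))
  cat(sprintf("  order concordance: %s, compression factor: %s\n",
              format(x$order_concordance), format(x$compression)))
  cat("  group peak times (ms):", paste(round(x$peak_times, 1),
                                        collapse = ", "), "\n")
  invisible(x)
}
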
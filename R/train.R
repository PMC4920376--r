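# Convert a spike_train_set into the 0-based (bin, channel) event stream the
# C++ simulator consumes, sorted by bin.
spike_events <- function(spikes, dt) {
  bins <- integer(0)
  chans <- integer(0)
  for (i in seq_len(spikes$n_channels)) {
    b <- as.integer(floor(spikes$spike_times[[i]] / dt))
    bins <- c(bins, b)
    chans <- c(chans, rep.int(i - 1L, length(b)))
  }
  o <- order(bins, chans)
  list(bin = bins[o], ch = chans[o])
}

# Fresh synaptic state for n synapses.
new_state <- function(n, w0 = NULL) {
  if (is.null(w0)) w0 <- numeric(n)
  stopifnot(length(w0) == n)
  list(w = as.numeric(w0), Am = numeric(n), As = numeric(n),
       Pt = numeric(n), U = 0)
}

# Run one contiguous segment through the compiled simulator, threading the
# synaptic state. spikes: spike_train_set; sched: conductance_schedule.
sim_segment <- function(spikes, sched, state, neuron, plasticity, dt,
                        learn = TRUE, record = FALSE) {
  ev <- spike_events(spikes, dt)
  n_bins <- round(spikes$duration / dt)
  gE <- rep_len(sched$g_E, n_bins)
  gI <- rep_len(sched$g_I, n_bins)
  cpp_sim_segment(ev$bin, ev$ch, n_bins, gE, gI,
                  state$w, state$Am, state$As, state$Pt, state$U, dt,
                  neuron$C, neuron$g_L, neuron$g_D, neuron$E_E, neuron$E_I,
                  neuron$phi_max, neuron$tau_m, neuron$tau_s,
                  plasticity$eta, plasticity$alpha, plasticity$tau,
                  learn, plasticity$postsynaptic_mode == "spike", record)
}

#' Train a single neuron on repeated input periods
#'
#' Runs the plasticity rule for `n_periods` repetitions of the trial period,
#' carrying synaptic traces and the low-pass filter state continuously
#' across period boundaries (so the convolution wraps, and a spike late in
#' period k shapes early period k+1). Input and somatic schedule may be
#' fixed, or vary per period (a list or a generator function of the period
#' index) for stochastic protocols.
#'
#' @param input a [spike_train_set()], a list of them (one per period), or
#'   `function(period)` returning one.
#' @param schedule a [conductance_schedule()], a list, or `function(period)`.
#' @param neuron a [neuron_params()].
#' @param plasticity a [plasticity_params()].
#' @param n_periods number of training periods.
#' @param dt grid step (ms).
#' @param w0 initial weights (default zeros).
#' @param metric_fn optional `function(trace, period)` evaluated on the
#'   recorded traces of every period; results are collected in `metrics`.
#'   Recording per period costs memory bandwidth, so traces are only
#'   recorded when `metric_fn` is given or for the final period.
#' @param warn_norm weight-norm bound; training aborts with a diagnostic
#'   error if `max(abs(w))` exceeds it (non-convergence guard).
#' @return list with final `weights`, the persistent `state`, the recorded
#'   trace of the last period (`phiU`, `phiV`, `U_trace`, `Vw`), and
#'   `metrics` (list over periods) when `metric_fn` was supplied.
#' @export
train_neuron <- function(input, schedule, neuron = neuron_params(),
                         plasticity = plasticity_params(), n_periods,
                         dt = 0.1, w0 = NULL, metric_fn = NULL,
                         warn_norm = 1e3) {
  get_input <- if (is.function(input)) input
    else if (inherits(input, "spike_train_set")) function(i) input
    else function(i) input[[i]]
  get_sched <- if (is.function(schedule)) schedule
    else if (inherits(schedule, "conductance_schedule")) function(i) schedule
    else function(i) schedule[[i]]
  spk1 <- get_input(1)
  state <- new_state(spk1$n_channels, w0)
  metrics <- if (is.null(metric_fn)) NULL else vector("list", n_periods)
  static_input <- inherits(input, "spike_train_set")
  last <- NULL
  for (i in seq_len(n_periods)) {
    spk <- if (static_input) spk1 else get_input(i)
    record <- !is.null(metric_fn) || i == n_periods
    res <- sim_segment(spk, get_sched(i), state, neuron, plasticity, dt,
                       learn = TRUE, record = record)
    state <- res[c("w", "Am", "As", "Pt", "U")]
    if (max(abs(state$w)) > warn_norm)
      stop("weight norm exceeded bound ", warn_norm,
           " at period ", i, ": learning appears divergent")
    if (!is.null(metric_fn))
      metrics[[i]] <- metric_fn(res, i)
    if (i == n_periods) last <- res
  }
  list(weights = state$w, state = state,
       trace = last[c("phiU", "phiV", "U_trace", "Vw")],
       metrics = metrics)
}

#' Probe a trained neuron with the somatic input silenced
#'
#' Replays the dendritic input with `g_E = g_I = 0` and learning frozen;
#' after learning, the firing rate read out this way represents the
#' discounted future rate of the somatic input applied during training. The
#' first `n_settle` periods warm up the wrapped synaptic traces and are
#' discarded.
#'
#' @param state synaptic state (or a result of [train_neuron()]).
#' @param input the dendritic input period to replay.
#' @param neuron,plasticity,dt as in [train_neuron()].
#' @param n_settle warm-up periods.
#' @return the recorded trace of the probe period.
#' @export
probe_neuron <- function(state, input, neuron = neuron_params(),
                         plasticity = plasticity_params(), dt = 0.1,
                         n_settle = 2) {
  if (!is.null(state$state)) state <- state$state
  n_bins <- round(input$duration / dt)
  silent <- conductance_schedule(numeric(n_bins), numeric(n_bins), dt)
  for (i in seq_len(n_settle)) {
    res <- sim_segment(input, silent, state, neuron, plasticity, dt,
                       learn = FALSE, record = FALSE)
    state <- res[c("w", "Am", "As", "Pt", "U")]
  }
  sim_segment(input, silent, state, neuron, plasticity, dt,
              learn = FALSE, record = TRUE)[c("phiU", "phiV", "U_trace", "Vw")]
}
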
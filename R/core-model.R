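#' Spike-response kernel of the postsynaptic potential
#'
#' Double-exponential kernel `c H(t) (exp(-t/tau_m) - exp(-t/tau_s))` with the
#' normalisation `c = 1/(tau_m - tau_s)` chosen so that the kernel integrates
#' to 1 over all time. Negative times return 0 (causality).
#'
#' @param t time (ms), vectorised.
#' @param params a [neuron_params()] object.
#' @return kernel values (1/ms).
#' @examples
#' t <- seq(0, 50, 0.1)
#' k <- psp_kernel(t)
#' sum(k) * 0.1  # ~1
#' @export
psp_kernel <- function(t, params = neuron_params()) {
  k <- (exp(-t / params$tau_m) - exp(-t / params$tau_s)) /
    (params$tau_m - params$tau_s)
  k[t < 0] <- 0
  k
}

#' Multi-channel presynaptic spike trains
#'
#' Container for per-synapse spike arrival times over one trial period.
#' Times must lie in `[0, duration)` and be strictly increasing per channel.
#' When `periodic = TRUE`, downstream convolutions wrap across the period
#' boundary so that a spike late in one period shapes the PSP early in the
#' next.
#'
#' @param spike_times list of numeric vectors, one per channel (ms).
#' @param duration trial length (ms).
#' @param periodic logical; is the pattern repeated periodically?
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spike_times, duration, periodic = FALSE) {
  stopifnot(is.list(spike_times), duration > 0)
  for (i in seq_along(spike_times)) {
    ti <- spike_times[[i]]
    if (length(ti)) {
      if (any(ti < 0 | ti >= duration))
        stop("spike times must lie in [0, duration); offending channel ", i)
      if (any(diff(ti) <= 0))
        stop("spike times must be strictly increasing; offending channel ", i)
    }
  }
  structure(list(spike_times = lapply(spike_times, as.numeric),
                 n_channels = length(spike_times),
                 duration = as.numeric(duration),
                 periodic = isTRUE(periodic)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n_spk <- sum(lengths(x$spike_times))
  cat(sprintf("Spike train set: %d channels, %d spikes over %g ms%s\n",
              x$n_channels, n_spk, x$duration,
              if (x$periodic) " (periodic)" else ""))
  invisible(x)
}

#' Somatic conductance schedule
#'
#' Excitatory and inhibitory conductance time series on a uniform grid.
#'
#' @param g_E,g_I conductances (nS) per bin; recycled to a common length.
#' @param dt grid step (ms).
#' @return An object of class `conductance_schedule`.
#' @export
conductance_schedule <- function(g_E, g_I = 0, dt = 0.1) {
  n <- max(length(g_E), length(g_I))
  g_E <- rep_len(as.numeric(g_E), n)
  g_I <- rep_len(as.numeric(g_I), n)
  if (any(g_E < 0) || any(g_I < 0)) stop("conductances must be non-negative")
  structure(list(g_E = g_E, g_I = g_I, dt = dt, n_bins = n),
            class = "conductance_schedule")
}

#' Dendritic potential from weighted presynaptic input
#'
#' Evaluates `V_w(t) = sum_i w_i sum_f kappa(t - t_f)` on the uniform grid
#' `t = 0, dt, 2 dt, ...` by explicit kernel evaluation (spike times are
#' snapped to the left edge of their bin, matching the state-variable
#' recursion used inside the simulator, where a spike first contributes
#' `kappa(dt)` one bin after arrival). For periodic trains the convolution
#' wraps: spikes of earlier copies of the period are included until the
#' kernel tail is negligible.
#'
#' @param weights numeric vector, one weight per channel.
#' @param spikes a [spike_train_set()].
#' @param dt grid step (ms).
#' @param params a [neuron_params()].
#' @return numeric vector of `V_w` on the grid.
#' @export
dendritic_potential <- function(weights, spikes, dt = 0.1,
                                params = neuron_params()) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (length(weights) != spikes$n_channels)
    stop("length(weights) must equal the number of channels (",
         spikes$n_channels, ")")
  n_bins <- round(spikes$duration / dt)
  tgrid <- (seq_len(n_bins) - 1) * dt
  v <- numeric(n_bins)
  n_wrap <- if (spikes$periodic)
    ceiling(25 * params$tau_m / spikes$duration) else 0
  for (i in seq_len(spikes$n_channels)) {
    w <- weights[i]
    if (w == 0) next
    for (tf in spikes$spike_times[[i]]) {
      tf <- floor(tf / dt) * dt
      for (m in 0:n_wrap)
        v <- v + w * psp_kernel(tgrid - tf + m * spikes$duration, params)
    }
  }
  v
}

#' Forward-Euler integration of the somatic potential
#'
#' Integrates `C dU/dt = -g_L U + g_D (V_w - U) + g_E (E_E - U) +
#' g_I (E_I - U)` with the explicit Euler scheme. The trace value at bin `k`
#' is the pre-step potential, i.e. `U[1] = U0`. An error is raised when the
#' step violates the stability condition `dt g_tot / C < 1`.
#'
#' @param params a [neuron_params()].
#' @param V_w dendritic potential per bin.
#' @param sched a [conductance_schedule()] on the same grid.
#' @param dt grid step (ms).
#' @param U0 initial somatic potential.
#' @return numeric vector of `U` on the grid.
#' @export
integrate_soma <- function(params, V_w, sched, dt = 0.1, U0 = 0) {
  stopifnot(inherits(sched, "conductance_schedule"))
  n <- length(V_w)
  gE <- rep_len(sched$g_E, n)
  gI <- rep_len(sched$g_I, n)
  gtot <- params$g_L + params$g_D + gE + gI
  Cms <- params$C * 1000  # nF -> nS * ms, so C/g_tot is a time in ms
  if (any(dt * gtot / Cms >= 1))
    stop("forward Euler unstable: dt * g_tot / C >= 1; reduce dt")
  U <- numeric(n)
  u <- U0
  for (k in seq_len(n)) {
    U[k] <- u
    u <- u + dt / Cms *
      (-params$g_L * u + params$g_D * (V_w[k] - u) +
         gE[k] * (params$E_E - u) + gI[k] * (params$E_I - u))
  }
  U
}

#' Steady-state decomposition of the somatic potential
#'
#' For slowly varying input the somatic potential is well approximated by
#' `U = lambda V*_w + U*` with nudging factor
#' `lambda = (g_L + g_D)/g_tot`, attenuated dendritic potential
#' `V*_w = g_D V_w / (g_L + g_D)` and attenuated somatic input
#' `U* = (g_E E_E + g_I E_I)/g_tot`. All arguments vectorise.
#'
#' @param V_w dendritic potential.
#' @param g_E,g_I somatic conductances (nS).
#' @param params a [neuron_params()].
#' @return list with components `lambda`, `V_star`, `U_star`, `U_approx`.
#' @export
steady_state_decomposition <- function(V_w, g_E, g_I = 0,
                                       params = neuron_params()) {
  if (any(g_E < 0) || any(g_I < 0)) stop("conductances must be non-negative")
  gtot <- params$g_L + params$g_D + g_E + g_I
  lambda <- (params$g_L + params$g_D) / gtot
  V_star <- params$g_D * V_w / (params$g_L + params$g_D)
  U_star <- (g_E * params$E_E + g_I * params$E_I) / gtot
  list(lambda = lambda, V_star = V_star, U_star = U_star,
       U_approx = lambda * V_star + U_star)
}

#' Instantaneous firing rate transfer function
#'
#' Piecewise-linear transfer `phi(U)`: 0 for `U < 0`, `phi_max U` for
#' `0 <= U <= 1`, saturating at `phi_max` above.
#'
#' @param U somatic potential (vectorised).
#' @param params a [neuron_params()].
#' @return firing rate (kHz).
#' @export
firing_rate <- function(U, params = neuron_params()) {
  params$phi_max * pmin(pmax(U, 0), 1)
}

#' Sample spikes from an inhomogeneous Bernoulli process
#'
#' Draws one independent Bernoulli variable per bin with success probability
#' `rate * dt` (the discrete-time realisation of an inhomogeneous Poisson
#' process) and returns the left-edge times of spiking bins.
#'
#' @param rate firing rate per bin (kHz).
#' @param dt bin width (ms); `rate * dt` must not exceed 1.
#' @param seed optional integer; when given, sampling is reproducible and the
#'   caller's RNG stream is left untouched.
#' @return numeric vector of spike times (ms).
#' @export
sample_spikes <- function(rate, dt = 0.1, seed = NULL) {
  p <- rate * dt
  if (any(p < 0)) stop("rates must be non-negative")
  if (any(p > 1)) stop("spike probability rate*dt exceeds 1; reduce dt")
  draws <- with_seed(seed, stats::runif(length(p)) < p)
  (which(draws) - 1) * dt
}
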
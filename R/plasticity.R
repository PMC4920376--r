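#' Low-pass filter a PSP trace
#'
#' Applies the normalised exponential filter
#' `PSPtilde(t) = (1/tau) integral_0^Inf exp(-s/tau) PSP(t-s) ds`,
#' discretised as the exact exponential-smoothing recursion
#' `y_k = a y_{k-1} + (1-a) x_k` with `a = exp(-dt/tau)` and zero history
#' before the first sample. `tau = 0` returns the input unchanged.
#'
#' @param psp numeric PSP time series.
#' @param tau filter time constant (ms), `>= 0`.
#' @param dt bin width (ms).
#' @return filtered series of the same length.
#' @export
lowpass_psp <- function(psp, tau, dt = 0.1) {
  stopifnot(tau >= 0)
  if (tau == 0) return(psp)
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * psp, a, method = "recursive"))
}

#' Per-synapse state of the plasticity rule
#'
#' @param weights synaptic weights.
#' @param psp current PSP value per synapse.
#' @param psp_tilde current low-pass filtered PSP per synapse.
#' @return An object of class `synapse_state`.
#' @export
synapse_state <- function(weights, psp = 0, psp_tilde = 0) {
  n <- length(weights)
  psp <- rep_len(psp, n)
  psp_tilde <- rep_len(psp_tilde, n)
  if (any(psp < 0) || any(psp_tilde < 0))
    stop("PSP traces must be non-negative")
  structure(list(weights = as.numeric(weights), psp = as.numeric(psp),
                 psp_tilde = as.numeric(psp_tilde)),
            class = "synapse_state")
}

#' One Euler step of the prospective-coding weight dynamics
#'
#' Advances the weights by
#' `dw_i = dt eta (alpha post PSPtilde_i - phi(V_dep) PSP_i)`, where `post`
#' is the instantaneous rate `phi(U)` in rate mode or the spike indicator
#' divided by `dt` in spike mode, and `V_dep` is the potential selected by
#' the depression variant (`V*_w` by default).
#'
#' @param state a [synapse_state()].
#' @param U somatic potential at this bin.
#' @param V_star attenuated dendritic potential at this bin.
#' @param p a [plasticity_params()].
#' @param neuron a [neuron_params()].
#' @param dt bin width (ms).
#' @param post_spike 0/1 spike indicator, required in spike mode.
#' @param lam nudging factor, required for the `nudged_dendritic` variant.
#' @param V_w raw dendritic potential, required for `raw_dendritic`.
#' @return the updated [synapse_state()].
#' @export
weight_step <- function(state, U, V_star, p, neuron = neuron_params(),
                        dt = 0.1, post_spike = NULL, lam = NULL, V_w = NULL) {
  stopifnot(inherits(state, "synapse_state"), inherits(p, "plasticity_params"))
  post <- if (p$postsynaptic_mode == "spike") {
    if (is.null(post_spike))
      stop("spike mode requires the post_spike indicator")
    post_spike / dt
  } else {
    firing_rate(U, neuron)
  }
  v_dep <- switch(p$depression_variant,
    attenuated_dendritic = V_star,
    nudged_dendritic = {
      if (is.null(lam)) stop("nudged_dendritic variant requires lam")
      lam * V_star
    },
    raw_dendritic = {
      if (is.null(V_w)) stop("raw_dendritic variant requires V_w")
      V_w
    })
  dw <- dt * p$eta *
    (p$alpha * post * state$psp_tilde - firing_rate(v_dep, neuron) * state$psp)
  state$weights <- state$weights + dw
  state
}

#' Effective discount time constant of the learned code
#'
#' The bootstrapping effect of predicting the own predictions stretches the
#' biophysical filter time constant `tau` to `tau_eff = tau / (1 - lam alpha)`:
#' the timescale over which the learned dendritic rate discounts future
#' somatic input.
#'
#' @param tau plasticity low-pass time constant (ms).
#' @param lam nudging factor in (0, 1].
#' @param alpha potentiation factor; `lam * alpha < 1` is required.
#' @return `tau_eff` (ms).
#' @examples
#' effective_time_constant(9, 1, 0.985)  # 600 ms
#' @export
effective_time_constant <- function(tau, lam, alpha) {
  if (lam * alpha >= 1)
    stop("divergent effective time constant: lam * alpha >= 1")
  tau / (1 - lam * alpha)
}

#' Effective time constant under depression-term variants
#'
#' @param tau plasticity low-pass time constant (ms).
#' @param lam nudging factor (used by `attenuated_dendritic`).
#' @param lam2 ratio `g_D / g_tot` (used by `raw_dendritic`).
#' @param alpha potentiation factor.
#' @param variant depression variant name, see [plasticity_params()].
#' @return `tau_eff` (ms).
#' @export
variant_time_constant <- function(tau, lam, lam2, alpha,
                                  variant = c("attenuated_dendritic",
                                              "nudged_dendritic",
                                              "raw_dendritic")) {
  variant <- match.arg(variant)
  denom <- switch(variant,
                  attenuated_dendritic = 1 - lam * alpha,
                  nudged_dendritic = 1 - alpha,
                  raw_dendritic = 1 - lam2 * alpha)
  if (denom <= 0) stop("divergent effective time constant for variant ",
                       variant)
  tau / denom
}

#' Largest admissible potentiation factor
#'
#' Weights stay bounded when the potentiation factor is positive but smaller
#' than the inverse of the largest nudging factor encountered during
#' training.
#'
#' @param max_lambda largest nudging factor, in (0, 1].
#' @return the bound `1 / max_lambda`.
#' @export
stability_bound <- function(max_lambda) {
  stopifnot(max_lambda > 0, max_lambda <= 1)
  1 / max_lambda
}
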
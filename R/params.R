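#' Biophysical parameters of the two-compartment neuron
#'
#' Bundles all constants of the neuron model: somatic capacitance, leak and
#' dendro-somatic coupling conductances, synaptic reversal potentials, the
#' maximal firing rate of the linear-saturating transfer function, and the
#' two time constants of the double-exponential spike-response kernel.
#' Potentials are unitless with rest at 0; taking rest to correspond to
#' -70 mV and a potential of 1 to -55 mV, the default reversal potentials
#' `E_E = 14/3` and `E_I = -1/3` map to 0 mV and -75 mV.
#'
#' @param C somatic capacitance (nF; with conductances in nS and time in ms,
#'   1 nF = 1000 nS ms, so the somatic time constant is
#'   `1000 C / g_tot` ms, about 0.53 ms at rest for the defaults).
#' @param g_L leak conductance (nS).
#' @param g_D dendro-somatic coupling conductance (nS).
#' @param E_E,E_I excitatory / inhibitory reversal potentials (unitless).
#' @param phi_max maximal firing rate (kHz).
#' @param tau_m,tau_s membrane and synaptic time constants of the
#'   spike-response kernel (ms); `tau_m > tau_s > 0` is required.
#'
#' @return An object of class `neuron_params`.
#' @examples
#' p <- neuron_params()
#' p$g_D / (p$g_L + p$g_D)  # dendritic attenuation factor
#' @export
neuron_params <- function(C = 1, g_L = 100, g_D = 1800,
                          E_E = 14 / 3, E_I = -1 / 3,
                          phi_max = 0.06, tau_m = 10, tau_s = 10 / 3) {
  stopifnot(C > 0, g_L > 0, g_D > 0, phi_max > 0)
  if (!(tau_m > tau_s && tau_s > 0))
    stop("kernel time constants must satisfy tau_m > tau_s > 0")
  if (!(E_I < 0 && E_E > 0))
    stop("reversal potentials must satisfy E_I < 0 < E_E")
  structure(list(C = C, g_L = g_L, g_D = g_D, E_E = E_E, E_I = E_I,
                 phi_max = phi_max, tau_m = tau_m, tau_s = tau_s),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Two-compartment neuron parameters\n")
  cat(sprintf("  C = %g nF, g_L = %g nS, g_D = %g nS\n", x$C, x$g_L, x$g_D))
  cat(sprintf("  E_E = %.4g, E_I = %.4g (unitless potentials)\n", x$E_E, x$E_I))
  cat(sprintf("  phi_max = %g kHz, tau_m = %g ms, tau_s = %g ms\n",
              x$phi_max, x$tau_m, x$tau_s))
  invisible(x)
}

#' Parameters of the prospective-coding plasticity rule
#'
#' @param alpha potentiation factor; must stay below
#'   [stability_bound()] of the largest nudging factor encountered for
#'   weights to remain bounded.
#' @param eta learning rate.
#' @param tau time constant (ms) of the additional low-pass filter applied to
#'   the postsynaptic potential in the potentiation term; `tau = 0` recovers
#'   the matched-window rule in which the dendrite predicts current rather
#'   than future somatic firing.
#' @param depression_variant which potential drives the depression term:
#'   `"attenuated_dendritic"` uses `phi(V*_w)` (the default rule),
#'   `"nudged_dendritic"` uses `phi(lambda V*_w)`, `"raw_dendritic"` uses
#'   `phi(V_w)`. The variants change the effective discount time constant,
#'   see [variant_time_constant()].
#' @param postsynaptic_mode `"rate"` uses the instantaneous rate `phi(U)` as
#'   the postsynaptic factor of potentiation; `"spike"` replaces it by a
#'   sampled spike indicator divided by dt, which agrees with rate mode in
#'   expectation but learns more slowly.
#'
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(alpha = 0.985, eta = 0.5, tau = 9,
                              depression_variant = c("attenuated_dendritic",
                                                     "nudged_dendritic",
                                                     "raw_dendritic"),
                              postsynaptic_mode = c("rate", "spike")) {
  stopifnot(alpha > 0, eta > 0, tau >= 0)
  structure(list(alpha = alpha, eta = eta, tau = tau,
                 depression_variant = match.arg(depression_variant),
                 postsynaptic_mode = match.arg(postsynaptic_mode)),
            class = "plasticity_params")
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("Prospective-coding plasticity parameters\n")
  cat(sprintf("  alpha = %g, eta = %g, tau = %g ms\n", x$alpha, x$eta, x$tau))
  cat(sprintf("  depression: %s, postsynaptic mode: %s\n",
              x$depression_variant, x$postsynaptic_mode))
  invisible(x)
}

# Evaluate code with a temporary RNG state seeded by `seed`; the caller's
# stream is restored afterwards. seed = NULL runs the code unchanged.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
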
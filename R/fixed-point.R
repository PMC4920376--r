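#' Fixed point of learning for a periodic environment
#'
#' Stationary dendritic rate implied by the plasticity rule for a periodic
#' somatic input rate: the exponentially discounted expectation of the
#' future somatic rate,
#' `f(t) = (alpha/tau) integral_0^Inf exp(-s/tau_eff) phi_Ustar(t+s) ds`,
#' with `tau_eff = tau / (1 - lam alpha)`. The integral is evaluated in the
#' time domain as a wrapped discrete convolution: the input is treated as
#' piecewise constant on the grid, the kernel is integrated exactly over
#' each bin, and the convolution runs over enough periods that the truncated
#' kernel tail is below `1e-8`. A spatially independent frequency-domain
#' route is available in [fourier_fixed_point()].
#'
#' @param phi_Ustar periodic somatic input rate on the grid (kHz), one
#'   period.
#' @param lam constant nudging factor.
#' @param alpha potentiation factor (`lam * alpha < 1`).
#' @param tau plasticity low-pass time constant (ms), `> 0`.
#' @param dt grid step (ms).
#' @return the stationary dendritic rate `phi(V*_w)` on the same grid.
#' @export
periodic_fixed_point <- function(phi_Ustar, lam, alpha, tau, dt = 0.1) {
  stopifnot(tau > 0)
  tau_eff <- effective_time_constant(tau, lam, alpha)
  n <- length(phi_Ustar)
  period <- n * dt
  rho <- exp(-dt / tau_eff)
  # exact integral of (alpha/tau) exp(-s/tau_eff) over the first bin
  h0 <- (alpha / tau) * tau_eff * (1 - rho)
  # enough full periods that exp(-s/tau_eff) < 1e-8 at the truncation point
  n_rep <- max(2L, ceiling(log(1e8) * tau_eff / period) + 1L)
  x <- rep(rev(phi_Ustar), n_rep)
  y <- as.numeric(stats::filter(h0 * x, rho, method = "recursive"))
  rev(utils::tail(y, n))
}

#' Fixed point of learning via Fourier modes
#'
#' Frequency-domain solution of the same stationary condition as
#' [periodic_fixed_point()]: each Fourier coefficient of the periodic
#' somatic rate is scaled by
#' `(alpha/tau) / ((1 - alpha lam)/tau - i 2 pi k / T)` and the result is
#' transformed back. Serves as an independent cross-check of the time-domain
#' convolution; the two routes agree up to the discretisation error of the
#' grid (exactly on the constant mode).
#'
#' @inheritParams periodic_fixed_point
#' @return the stationary dendritic rate on the same grid.
#' @export
fourier_fixed_point <- function(phi_Ustar, lam, alpha, tau, dt = 0.1) {
  stopifnot(tau > 0)
  if (lam * alpha >= 1) stop("divergent fixed point: lam * alpha >= 1")
  n <- length(phi_Ustar)
  period <- n * dt
  ghat <- stats::fft(phi_Ustar)
  k <- 0:(n - 1)
  k <- ifelse(k > n / 2, k - n, k)  # signed mode numbers
  denom <- (1 - alpha * lam) / tau - 1i * 2 * pi * k / period
  fhat <- (alpha / tau) * ghat / denom
  f <- stats::fft(fhat, inverse = TRUE) / n
  Re(f)
}
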
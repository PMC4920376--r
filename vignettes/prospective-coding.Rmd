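---
title: "Prospective coding in two-compartment neurons: model, theory and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prospective coding in two-compartment neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procode)
```

## The model

A neuron is reduced to two compartments. The dendrite collects input
through plastic synapses: each presynaptic spike at synapse $i$ adds a
postsynaptic potential with the double-exponential spike-response kernel

$$\kappa(t) = c\,H(t)\left(e^{-t/\tau_m} - e^{-t/\tau_s}\right),
\qquad \tau_m = 10\ \mathrm{ms},\ \tau_s = 10/3\ \mathrm{ms},$$

normalised by $c = 1/(\tau_m - \tau_s)$ so that $\int \kappa = 1$. The
dendritic potential is the weighted sum
$V_w(t) = \sum_i w_i \mathrm{PSP}_i(t)$. The soma is a conductance-based
leaky integrator,

$$C\dot U = -g_L U + g_D (V_w - U) + g_E(t)(E_E - U) + g_I(t)(E_I - U),$$

with $C = 1$ nF, $g_L = 100$ nS, $g_D = 1.8\ \mu$S, $E_E = 14/3$,
$E_I = -1/3$. Potentials are unitless with rest at 0 (rest may be read as
$-70$ mV and a potential of 1 as $-55$ mV). Output spiking is an
inhomogeneous Poisson process with the piecewise-linear rate
$\varphi(U) = \varphi_{\max}\min(\max(U,0),1)$, $\varphi_{\max} = 60$ Hz.

For slowly varying conductances the somatic potential is well approximated
by its steady state $U \approx \lambda V_w^* + U^*$, with the attenuated
dendritic potential $V_w^* = \frac{g_D}{g_L+g_D}V_w$, the attenuated
somatic input $U^* = (g_E E_E + g_I E_I)/g_{tot}$ and the *nudging factor*
$\lambda = (g_L+g_D)/g_{tot} \in (0,1]$: $\lambda = 1$ means the soma is
driven by its dendrite alone.

## The plasticity rule

Dendritic weights follow the differential-Hebbian dynamics

$$\dot w_i = \eta\left(\alpha\,\varphi(U)\,\widetilde{\mathrm{PSP}}_i
  - \varphi(V_w^*)\,\mathrm{PSP}_i\right),$$

where $\widetilde{\mathrm{PSP}}$ is the PSP low-pass filtered with time
constant $\tau$ (unit DC gain). The potentiation window is therefore
*slightly wider* than a PSP; that width is the whole point. At a
stationary point of learning in a periodic environment the dendritic rate
equals the expected future discounted somatic input rate

$$\varphi(V_w^*(t)) = \frac{\alpha}{\tau}\int_0^\infty
  e^{-s/\tau_{\mathrm{eff}}}\varphi(U^*(t+s))\,ds,
  \qquad \tau_{\mathrm{eff}} = \frac{\tau}{1-\lambda\alpha}.$$

Predicting one's own predictions (bootstrapping) stretches the biophysical
$\tau$ by $1/(1-\lambda\alpha)$: $\tau = 9$ ms with $\alpha = 0.985$ and
$\lambda = 1$ gives $\tau_{\mathrm{eff}} = 600$ ms, a behavioural
timescale. The potentiation factor must stay below $1/\max_t\lambda(t)$
(`stability_bound()`) or weights grow without bound. With $\tau \to 0$ and
$\alpha = 1$ the rule degenerates to dendritic prediction of *current*
somatic firing (the matched-window rule); `variant_time_constant()` gives
the corresponding $\tau_{\mathrm{eff}}$ when the depression term uses the
nudged or the raw dendritic potential instead of $V^*_w$.

`weight_step()` exposes a single Euler step of this rule;
`train_neuron()` runs the compiled simulator, which carries two
exponential state variables per synapse (the exact discrete update of the
double-exponential kernel) rather than explicit convolutions, and keeps
all synaptic traces continuous across period boundaries so the
convolution wraps.

## Analytic fixed points as oracles

`periodic_fixed_point()` evaluates the discounted-future integral by a
wrapped time-domain convolution (input treated as piecewise constant, the
kernel integrated exactly per bin, tail truncated below $10^{-8}$);
`fourier_fixed_point()` solves the same stationarity condition by
per-mode division with the continuous transfer function. The two routes
discretise the same operator differently: they agree exactly on the
constant mode and to $O(\mathrm{d}t\,k/T)$ on oscillatory modes
(about $10^{-4}$ relative per mode at $\mathrm{d}t = 0.1$ ms and a 2 s
period), which is why the cross-check test asserts $10^{-3}$ agreement on
band-limited inputs rather than machine precision.

In the stochastic setting the environment is a latent irreducible Markov
chain (`markov_environment()`); dendritic PSP values and the somatic rate
$r_I$ are functions of the state. With the discounting operator
$A = \alpha(I-\gamma T)^{-1}$ (row sums $\alpha/(1-\gamma)$), the learned
code solves $r_V = (I - A\Lambda)^{-1} A\, r_I$, equivalently a
$\gamma_{\mathrm{eff}}$-discounted expectation with
$\gamma_{\mathrm{eff}} = \gamma/(1-\lambda\alpha)$, provided
$\lambda\alpha < 1-\gamma$. `mean_ode_trajectory()` integrates the
averaged weight dynamics and certifies convergence with the Lyapunov
function $L(w) = \tfrac12\|w - w^*\|^2$ ($w^*$ the projection onto the
fixed-point set). The correspondence with a deterministic $N$-cycle is
exact up to the per-step normalisation: the continuous-time code equals
$(1-\gamma_{\mathrm{eff}})$ times the discrete discounted sum, because the
continuous filter is normalised by $1/\tau$ while the discrete trace is
not.

The learned code is the TD($\lambda$) value function: `value_function()`
with $\gamma_{TD} = \gamma_{\mathrm{eff}}$ reproduces
`markov_fixed_point()` exactly, `td_lambda_learn()` converges to it by
sampling, the eligibility trace coincides with the rule's low-pass PSP
trace when $\lambda_{TD}\gamma_{TD} = \gamma$, and
`td1_equivalence_check()` shows that with the dendritic delta error the
two rules move along the same weight trajectory up to a telescoping
boundary term of order $\eta$ (the check reports both the raw discrepancy,
which halves with $\eta$, and the residual after subtracting the analytic
boundary).

## Synthetic inputs

All generators are pure functions of their parameters and a seed.

* `orthogonal_pattern()` — one spike per synapse, evenly spaced; the
  sparsest input that still covers every PSP window when there are a few
  hundred synapses.
* `frozen_poisson()` — one Poisson draw, replayed identically each trial.
* `inhomogeneous_poisson()` — fresh Bernoulli sampling per trial from
  given rate profiles; `smooth_rate_profiles()` supplies periodic,
  temporally rich profiles.
* `stm_templates()` / `stm_traces()` — the short-term-memory stand-in for
  a recurrent reservoir: per-neuron template trajectories from a mean-zero
  Ornstein--Uhlenbeck process ($1/\theta_1 = 1000$ ms, $\sigma_1 = 1$),
  and per-trial rates relaxing towards
  $\mu_s(t) = (1-\sigma(t))r^s(t) - \sigma(t)/2$ with
  $1/\theta_2 = 100$ ms and noise variance dropping from 1 to 0.1 at
  stimulus onset (onset quenches variability; between trials the rates are
  template-independent). The SDEs are integrated by Euler--Maruyama. The
  parameters are taken literally in ms units, which makes the stationary
  template variance $\sigma_1^2/2\theta_1 = 500$: far above the linear
  range of $\varphi$, so STM neurons effectively switch between silence
  and saturated firing on the template's slow timescale. That is still
  temporally rich, label-specific input, and it is what the stated
  parameters give; `ou_params()` lets the user rescale if graded rates
  are wanted.
* `fig5_conductance()` — the sinusoidal somatic drive
  $g_E(t) = 6(1-\sin\omega t\,\sin 2\omega t\,\cos 4\omega t)$ nS,
  $\omega = 2\pi/2$ s.
* `sequential_stimulation()` / `probabilistic_event()` — group pulses for
  the recurrent protocol and Bernoulli thinning of a training event.

What the generators do *not* emulate: trial-to-trial drift of templates,
correlations between afferents beyond a shared label, conduction delays,
and any refractoriness — passing tests say nothing about those features
of real data.

## Protocols, their parameters, and deliberate choices

**Anticipatory ramp** (`run_ramp_experiment()`): 2 s period, somatic pulse
$g_E = 15$ nS during the final 200 ms, weights from zero, probe with the
soma silenced. Defaults $\tau = 9$ ms, $\alpha = 0.985$ ($\alpha$ is not
printed for these protocols; it is recovered by inverting
$\tau_{\mathrm{eff}} = \tau/(1-\lambda\alpha)$ at the stated
$\tau_{\mathrm{eff}} = 600$ ms with $\lambda = 1$), $\eta = 50$ for the
sparse single-spike pattern and $\eta = 0.5$ otherwise. The ramp fit
window is 600--1800 ms, excluding the pulse; the amplitude window is
1500--1800 ms; both are configurable.

At convergence the simulated code tracks the fixed-point curve with
correlation $> 0.999$, but deviates by about 6--7% relative RMS with a
fitted time constant near 550 ms rather than 600 ms. This is not a
numerical artefact (it is unchanged at half the time step): the
fixed-point theory substitutes the *steady-state* somatic potential,
discarding the somatic lag $\tau_C = C/g_{tot} \approx 0.53$ ms. The lag
enters the bootstrapped loop and shifts the stationary point to
approximately $(\tau - \alpha\tau_C)/(1-\lambda\alpha) \approx 565$ ms,
and the finite synapse basis (500 single-spike PSPs) shifts it further to
$\approx 550$ ms — confirmed by solving the stationarity condition
exactly in the PSP basis. A 0.5 ms biophysical detail is amplified
67-fold; the theory is an approximation precisely where the model is most
interesting. At large learning rates a second bias appears: with
$\eta\,\mathrm{d}t$ of order one per bin the discrete weight dynamics
overshoots the ODE fixed point's amplitude (markedly at $\eta = 50$ with
dense input), while shape and correlation are preserved.

**Time-series advancement** (`run_advancement_experiment()`): frozen
Poisson input against the sinusoidal drive; the advancement is the lag of
the circular cross-correlation peak between the learned rate and the rate
the somatic input alone would produce. It grows with $\alpha$. The
matched-window control ($\tau = 0$, $\alpha = 1$) is run with balancing
inhibition $g_I = 4 g_E$, as in the pulse protocol's control: without it,
weak nudging makes the $\alpha = 1$ fixed point ill-conditioned (gain
$1/(1-\lambda)$) and the tiny somatic lag is amplified into a spurious
large delay. The control uses $\eta = 10$; at $\eta = 50$ the marginally
stable $\alpha = 1$ dynamics drifts.

**Delayed paired associate** (`run_paired_associate()`): STM activity
projects onto three readout neurons; targets drive the soma
($g_E = 5$ nS for the preferred target, 2.5 nS for the graded readout)
1.5 s after sample onset for 200 ms; intertrial intervals are uniform on
3--10 s; the probe metric is the mean rate in the last 200 ms of the
delay, with learning frozen and the soma silent. Readouts anticipate
their own target's somatic drive, so the ramp amplitude is
sample-selective.

**Recurrent replay** (`run_recurrent_replay()`): all-to-all network
without autapses, groups stimulated sequentially (100 ms, 20 nS, 300
sweeps, training pulses contiguous and periodic). Two parameters the
protocol does not pin down had to be chosen here. First, the learning
rate: with $\eta = 0.5$ the driven rates (≈3 Hz) build forward weights an
order of magnitude too weak for autonomous replay within 300 sweeps; we
follow the stated principle of raising the learning rate when
presynaptic rates are low and use $\eta = 3$ at 25 neurons per group
($\eta = 1.5$ at 50, keeping the dendritic drive per neuron comparable).
Second, recall: a strong brief pulse to group 1 (500 nS, 20 ms) ignites
the sequence; replay order and speed are measured on group rates averaged
over 8 recall probes *with weights frozen during the probes* — learning
stays on throughout training, but a repeated strong burst with plasticity
on would imprint direct group-1 connections onto every responsive neuron
and corrupt the very timing being measured. Order concordance is the
Kendall correlation between group peak times and the training order;
compression is the training span over the replay span between the first
and last group peaks. If no group beyond the first responds, both are
reported as `NA` rather than an error.

## Numerical choices

* Forward Euler at $\mathrm{d}t = 0.1$ ms everywhere (stability guard
  $\mathrm{d}t\,g_{tot}/C < 1$); traces are bin-left-aligned; a spike
  binned at $k$ first contributes $\kappa(\mathrm{d}t)$ at bin $k+1$.
  Within a bin the somatic update is applied first so that every factor of
  the weight update is evaluated at the same grid time.
* The low-pass PSP filter is the exact exponential-smoothing recursion;
  $\tau = 0$ returns the input. Geometric series in the theory module are
  computed by linear solve with truncated-sum cross-checks (truncation
  $10^{-12}$; kernel tails $10^{-8}$).
* The mean-ODE Euler step defaults to half the inverse spectral radius of
  the linear update map; the $B\Pi$ trivial-kernel assumption is realised
  in tests by full-column-rank $B$. The stationary distribution is
  computed by eigen-decomposition and validated, never trusted from input.
* No somatic reset after output spikes: spiking is a pure Poisson readout
  of $\varphi(U)$, consistent with how the rate enters the learning rule.

## Problem sizes used by the test-suite

The suite runs the ramp protocol at its published size (500 synapses, 500
periods; 1000 afferents for the low-rate variant), the advancement sweep
at 400 synapses and 150 periods, the replay at 4 groups of 25 for 300
sweeps, and the paired-associate task at 100 STM neurons and 40 trials
with 3--5 s intervals. These are the package's default desk scales; the
figure presets under `inst/configs/` carry the full published sizes.

## Known limitations

* The fixed-point comparison inherits the steady-state approximation's
  blind spot for the somatic lag (above): at
  $\tau_{\mathrm{eff}}/\tau \approx 67$ the theory curve is a few percent
  off the true stationary point of the simulated model.
* Nonlinear-transfer fixed points are only characterised to first order
  (affine shifts); the module reports but does not certify them.
* The STM process replaces a recurrent reservoir by construction; nothing
  here validates that a spiking reservoir would produce equivalent
  traces.
* The recurrent protocol's replay regime depends on free parameters
  ($\eta$, recall amplitude) that the package fixes by the analysis
  above; other choices can produce decaying cascades whose deep-group
  timing is shot-noise limited.
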
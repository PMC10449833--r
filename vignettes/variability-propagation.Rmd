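---
title: "Propagating trial-to-trial input variability through a spiking cortical microcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating trial-to-trial input variability through a spiking cortical microcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Cortical responses differ from trial to trial even under identical stimuli.
`spikevar` treats this variability as a property that the local circuit
actively *transforms*: per-trial fluctuations in the rates of feedforward
inputs to the excitatory (E), PV, and SST populations form a
three-dimensional "input cloud", and the circuit maps that cloud through its
(generally non-linear) population transfer-function into an output
distribution. The geometry of the mapping — how the cloud lies relative to
the iso-firing-rate surfaces of the transfer-function — decides whether the
across-trial variance of the excitatory output is amplified or quenched.
Three factors of the input distribution are studied separately: the mean
vector, the *balance* (signed ratio of two channels' variances, with sign
given by their correlation), and the pairwise covariances.

## Model

### Neurons

Each neuron is an adaptive exponential integrate-and-fire (AdEx) unit with
conductance-based synapses:

$$C_m \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_{th})/\Delta_T}
  - g_e(t) (V - E_e) - g_i(t) (V - E_i) - w + I_e,$$
$$\tau_w \dot w = a (V - E_L) - w.$$

On spike detection, $V \leftarrow V_r$, $w \leftarrow w + b$, and the neuron
is refractory (V clamped at $V_r$) for $t_r = 2$ ms. Per-population
constants are in `neuron_params()`. PV cells have no adaptation block and no
exponential term: they are plain leaky integrate-and-fire neurons with a
hard threshold at $V_{th}$. For AdEx populations a spike is detected at
$V \ge V_{th} + 5\Delta_T$, the usual numerical stand-in for the divergence
of the exponential upswing.

Synaptic conductances follow a single decaying exponential: each presynaptic
spike adds its peak conductance instantaneously, decay constants are the
per-target `tau_e` / `tau_i`, and contributions superpose additively.

### Network

`network_config()` encodes the default microcircuit: 3600 PC, 480 PV, 360
SST, 360 VIP neurons, Bernoulli connectivity per population pair,
log-normal weight scaling (meanlog 0, sdlog 1) around per-pair base
conductances, and a uniform 2 ms conduction delay. Weights are clipped so
that the single-event PSP at a −55 mV holding potential never exceeds
0.5 mV (EPSP) or 2.0 mV in magnitude (IPSP); `psp_peak()` computes the
deflection by integrating the subthreshold dynamics with the leak anchored
at the holding potential, and `conductance_cap()` inverts it. Two
degenerate configurations — a single weakly coupled excitatory population
(`one_pop_config()`) and an E–I pair (`ei_config()`) — run through the same
engine and are used to expose the monotone one-dimensional and the
two-dimensional transfer-function pictures.

Two connectivity-table cells (SST→SST and VIP→VIP) specify a connection
probability without a base conductance; the package defaults both to
0.07 nS, the same-row inhibitory conductance onto the other interneuron
class, and exposes the choice in the config.

### Drive and trial protocol

Every neuron receives 20 independent Poisson sources at a per-population
rate, through 50 nS excitatory synapses; defaults are the baseline rates
(16.0, 90.0, 9.3, 12.0) Hz for (PC, PV, SST, VIP). Because the sources are
independent and homogeneous, the engine realizes them as one equivalent
Poisson process at 20× the rate per neuron, which is statistically
identical and O(1) per neuron. A trial lasts 1000 ms: 250 ms preparation
from the cold start (discarded), stimulus onset (the switch from baseline
to baseline-plus-modulation rates, state carried across), 250 ms settling,
and a 500 ms steady-state measurement window. The VIP modulation is fixed
at zero, making the modulation space three-dimensional.

### Numerics

Fixed step `dt = 0.1` ms. Conductances decay by the exact per-step
exponential factor (this removes the stiffness of the 0.2 ms excitatory
decay); V and w advance by forward Euler; recurrent spikes are delivered at
the first grid time at or after emission + delay (2 ms is an exact multiple
of dt, so there is no interpolation ambiguity). The adaptation current
continues to relax while V is clamped during refractoriness. The engine is
bitwise deterministic given its seed; connectivity, weights, input spikes
and input clouds draw from separately derived seed streams so each
stochastic layer can be reproduced in isolation.

One caveat worth knowing: with a synaptic decay (0.2 ms) comparable to the
step, the forward-Euler voltage update integrates each synaptic transient
with a step-dependent effective charge, so measured rates in the
fluctuation-driven regime shift noticeably with `dt`. The error contracts
as `dt` shrinks (and the tests assert exactly that), but quantitative rate
values should be read as properties of the scheme at `dt = 0.1` ms.

## The calibration caveat

The parameter table carries a capacitance footnote in inconsistent units;
the package defaults to $C_m = 200$ pF, which gives a physiological ~10 ms
membrane time constant for PC. With the constants as printed and the
exponential synapse kernel, the stated baseline drive does *not* reproduce
the nominal in-vivo-like operating rates (≈2.5 Hz E/SST, ≈14 Hz PV/VIP):
sweeping $C_m$ over 20–2000 pF and applying charge-equivalent kernel
rescalings never yields that pattern, because (a) VIP requires ≈2.7× its
stated drive to reach 14 Hz while PV requires ≈1.2×, and (b) at 14 Hz the
PV→PC inhibitory current is ≈3× the external excitatory current onto PC, a
ratio invariant to $C_m$ and to global charge scaling. The corresponding
acceptance check is therefore expected to fail, and the package reports the
rates the model actually produces. All variability analyses instead anchor
at operating points (below) where the populations respond gradedly.

## Transfer-function estimation

`sweep_tf()` measures steady-state rates of all four populations on a
lattice of modulations, averaging over repetitions; nodes whose final input
rate would be negative are carried as `NA`. `interpolate_tf()` evaluates
the trilinear interpolant (exact at nodes, continuous across cells, no
extrapolation — out-of-hull queries error). `iso_rate_set()` extracts
iso-firing-rate point sets by dense rejection sampling of the interpolant,
which is simpler than a marching-cubes surface and sufficient for
cloud-alignment analyses.

The default lattice (`epsv_grid_axes()`) spans
$\Delta\lambda_E \in [16, 40]$, $\Delta\lambda_P \in [-30, 30]$,
$\Delta\lambda_S \in [0, 60]$ Hz on a 5×5×5 grid — the region where, under
the default drive, E fires gradedly (onset near
$\Delta\lambda_E \approx 20$), PV spans suppression to strong recruitment,
and SST overcomes PV inhibition at high drive. A full sweep at 2
repetitions takes a few minutes of CPU; denser axes are a drop-in change.

Operating regimes are located with `find_regime_presets()`: among lattice
nodes whose excitatory rate exceeds a floor (1 Hz), it anchors the
PV-dominated point at the node maximizing normalized PV-minus-SST rate,
then finds SST-dominated and mixed points with approximately matched
excitatory rate. On the default grid (match tolerance 0.35, needed at this
lattice coarseness) this gives the stored `epsv_presets()`:
PV-dominated (40, 0, 30), SST-dominated (40, −30, 60), mixed (28, −15, 60).

## Variability propagation

Two routes compute the across-trial output covariance:

- `map_through_tf()` — sample an input cloud (default 10000 points) from
  the 3-D normal `input_distribution()`, clip points that would push a
  final rate below zero to the zero boundary, map every point through the
  interpolated transfer-function, and take the sample covariance of the
  mapped (E, P, S) rates. If more than 5% of the cloud leaves the lattice
  hull the mapping aborts (the distribution is too wide for the grid);
  points below that fraction are dropped and counted rather than clamped,
  which would bias the variance toward boundary values.
- `simulate_trial_covariance()` — one cloud draw per trial sets that
  trial's modulation; each trial runs the full 1000 ms protocol; the
  covariance of the steady-state rates across trials (100 in the full
  protocol, 30 in the desk-scale checks) is returned.

`sweep_mean_variability()` and `sweep_factor_variability()` repeat the
mapped route over lattices of means, pairwise covariances, or balance
factors (under a fixed total variance, the variance split is derived from
the signed balance ratios and a negative balance is realized as a negative
covariance). Covariance matrices that are not positive semidefinite
(smallest eigenvalue below −1e−10 × largest) are rejected and masked, never
silently repaired.

In the PV-dominated regime the E and PV channels pull the excitatory rate
in opposite directions, so a positive E–P input covariance aligns the cloud
with the iso-rate direction and *reduces* the excitatory output variance —
the package's simulated check finds var$_E$ dropping from ≈1.1 to ≈0.4 Hz²
when $\sigma^{in}_{EP}$ goes from 0 to 0.5 Hz² at fixed variances
diag(1.8, 0.6, 0.6) Hz².

## What the generator does and does not emulate

The synthetic drive reproduces homogeneous Poisson statistics at stated
rates and the multivariate-normal trial structure with exact covariance
control (the tests recover σ entrywise to 3% at n = 10⁵). It does not
emulate serially correlated or oscillatory inputs, within-trial rate
modulation, or spike-level input correlations — so passing tests say
nothing about regimes where the asynchronous-irregular assumption behind
the single-neuron transfer-function breaks down (e.g. network
oscillations).

## Problem sizes used by the tests

The unit tests run scaled-down realizations (tens to hundreds of neurons,
sub-second protocols) chosen to exercise every code path; the acceptance
checks run the full 4800-neuron network for one 2.25 s baseline trial and
for 2 × 3 × 30 one-second trials of the covariance-effect comparison, and
the delta-method and interpolation oracles run on synthetic analytic grids.

## Known limitations

- The printed parameter set and the stated baseline operating point are
  mutually inconsistent under the exponential-kernel reading implemented
  here (see the calibration caveat); absolute rates should not be compared
  against in-vivo numbers without re-calibration.
- Trilinear interpolation underestimates curvature between lattice nodes;
  mapped variances inherit that bias where the transfer-function is
  strongly curved at the cloud scale.
- The PSTH bin width is a free display parameter (default 10 ms).
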
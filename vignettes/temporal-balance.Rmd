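---
title: "Temporal balance in excitatory-inhibitory networks: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal balance in excitatory-inhibitory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eibalance)
```

## The model

Cortical circuits keep recurrent excitation and inhibition in close
balance: the long-term averages cancel, and the interesting dynamics
live in the transients. `eibalance` implements a two-population
rate model of such a circuit in which the excitatory projections carry
two receptor components with very different kinetics — fast AMPA
(decay `tau_ampa`, 5 ms by default) and slow NMDA (`tau_nmda`, 100 ms) —
while inhibition acts through GABA (10 ms). The state variables are the
population rates `Re`, `Ri` (membrane time constants `tau_e` = 20 ms,
`tau_i` = 10 ms) and one first-order synaptic activation per projection
and receptor type, eight states in all:

```
tau_e  dRe/dt = -Re + Jee_ampa See_ampa + Jee_nmda See_nmda - Jei Sei + I(t)
tau_i  dRi/dt = -Ri + Jie_ampa Sie_ampa + Jie_nmda Sie_nmda - Jii Sii
tau_l  dS/dt  = -S + R_presynaptic
```

The six projection strengths are generated from four parameters
(`network_params()`): the base strength `w`, the inhibitory ratio `k`,
the NMDA fraction `q`, and the key control parameter `dq`, which shifts
the NMDA fraction of the excitatory-to-excitatory (EE) projection only:
`Jee_ampa = (1-q-dq) w`, `Jee_nmda = (q+dq) w`, `Jie_ampa = (1-q) w`,
`Jie_nmda = q w`, `Jei = Jii = k w`. The shift is applied to EE rather
than subtracted from IE; the two choices give the same dynamics (the
test suite checks the dominant poles agree), because only the
*relative* timing of the EE and IE pathways matters.

Two inequalities summarize stability at leading order in the synaptic
strength. The classical *balance condition*
(`balance_lhs()`) compares the strengths of negative and positive
feedback; the parameterization satisfies it with exact equality, by
construction. The *temporal balance condition*
(`temporal_balance_lhs()`) weights each AMPA strength by the NMDA decay
time and vice versa; under the parameterization it collapses to
`k w^2 dq (tau_nmda - tau_ampa)`, so `dq` alone decides whether
strength-weighted negative feedback is fast enough. Both are reported
as diagnostics; every actual stability verdict in the package comes
from the exact eigenvalues of the full state matrix
(`build_linear_system()`, `stability_report()`), because the printed
critical values of `dq` reflect the exact characteristic polynomial,
not the leading-order conditions.

### What `dq` does

With the canonical `w = 30`, `k = 1.2`, `q = 0.3`:

* `dq < -0.018` (approximately): a complex pole pair crosses the
  imaginary axis at about 1.9 Hz — the network destabilizes through a
  *delta-band* oscillation. `find_imag_axis_crossing()` locates the
  crossing by bisection on the maximum real part.
* small negative `dq`: the two slowest real poles merge and become a
  damped complex pair (`find_critical_damping()`); damped delta
  oscillations appear. This is the fastest-responding stable regime.
* `dq = 0`: feedback is exactly balanced in time; the response is
  overdamped.
* increasing `dq > 0`: the dominant real pole slows dramatically — the
  network time constant `tau_n = -1/Re(lambda_dom)` grows from tens of
  milliseconds to seconds, a regime suitable for integration and
  working-memory-like persistence.
* `dq` slightly below 0.15: a fast pair crosses the imaginary axis near
  58 Hz — a *gamma-band* instability driven by the slow NMDA positive
  feedback.

The response speed is quantified by the 10%-to-90% rise time of the
step response (`rise_time()`), computed from the analytic step response
with the steady state taken from `-A^{-1}B` (never from the last
simulated sample). When one real eigenvalue dominates,
`rise_time = ln(9) tau_n` to good accuracy, and the suite enforces this
as a property.

### The spring reduction

A one-population reduction with instantaneous membrane and AMPA
kinetics behaves as a damped harmonic oscillator,
`R'' + 2 zeta omega0 R' + omega0^2 R = I(t)`, with
`omega0 = 1/sqrt(tau_e tau_nmda)` — 3.56 Hz for the standard constants,
which is why the proximity of fast cortical networks to instability
shows up specifically as *delta* oscillations. Rather than reproducing
the closed-form reduction symbolically, `fit_spring_from_poles()` maps
any dominant complex pair to the spring with the same poles
(`omega0 = |lambda|`, `zeta = -Re(lambda)/|lambda|`); this has
identical observable behavior and avoids committing to unprinted
algebra. The fitted `omega0` of the reduced network approaches the
formula as `tau_ampa` is removed, and the extra time constants of the
full network lower it — both checked in the tests.

## Numerical choices

* **Integrator.** Fixed-step classical 4th-order Runge-Kutta
  (`dt` = 0.1 ms by default) for all rate models: deterministic,
  reproducible, and far more accurate than needed for time constants of
  5 ms and above. Halving `dt` moves terminal states by less than
  1e-8 relative.
* **Rectification.** The simulated network clips `Re`, `Ri` at zero
  after each step (biological rates are non-negative). It is off in
  linear-analysis comparisons, where superposition must hold exactly,
  and off by default in the reduced model, whose undamped regime only
  sustains oscillation in the linear system.
* **Smoothed steps.** The canonical stimulus is a step (5 Hz for the
  linear network, 10 Hz with depression) filtered by a "100 ms Gaussian
  kernel". The kernel width is interpreted as the standard deviation,
  truncated at four sigma and renormalized; the source does not state
  whether the figure means sigma or full width, and sigma is the more
  common convention. Rise-time *targets*, by contrast, use an ideal
  unfiltered unit step: the published fastest rise time of 52.5 ms
  could not survive a 100 ms kernel, which settles the ambiguity in
  favor of ideal steps for those quantities.
* **Root finding.** Bisection throughout: on the maximum pole real part
  for instabilities and on the count of complex poles for the
  critical-damping transition, with a `dq` tolerance of 1e-6. The
  max-real-part is continuous but not smooth, so bracketing methods are
  the robust choice. Complexity of a pole is judged relative to its
  magnitude (threshold 1e-5 |lambda|) because numerically degenerate
  real eigenvalues acquire spurious imaginary parts of order
  sqrt(machine epsilon).
* **Near-defective systems.** Exactly at critical damping the
  eigenvector basis degenerates; the analytic step response falls back
  to RK4 integration when the eigenvector condition number exceeds
  1e10.

## Short-term depression

Excitatory synapses depress: efficacy `x` recovers toward 1 with time
constant `tau_r` and is consumed at `u x R(t)` (`std_derivative()`).
Receptor-specific usage rates split around the base rate `u` turn
depression into a *time-varying* temporal-balance perturbation. The
package's sign convention is `u_ampa = u + du`, `u_nmda = u - du`:
positive `du` depresses EE AMPA harder, raising the effective NMDA
fraction of that projection (the slow, stable direction), and negative
`du` pushes it toward the AMPA-dominated delta instability — so `du`
acts with the same sign as a static `dq`. The source material defines
the split with the opposite sign next to figure captions that describe
the dynamics implemented here; the dynamics are the authoritative part
(they, not the sign of a symbol, carry the scientific claim), and the
common starting point of all depression trajectories at
`(We, dq_eff) = (w, 0)` fixes the weight equations as printed:
the effective EE weights are `x_ampa w/2` and `x_nmda w/2`, while the
IE projections carry the mean `(x_ampa + x_nmda) w/4` on each receptor.
With the NMDA fraction fixed at `q = 0.5` this construction keeps the
strength balance identity exact at every instant, so the depression
state moves the network only along two axes: total excitatory strength
`We` and effective shift
`dq_eff = x_nmda/(x_ampa + x_nmda) - 1/2` (`effective_position()`).
Defaults `u = 0.2`, `tau_r = 500 ms` are central values for cortical
depressing synapses. `tau_r` is shared between receptor types (the
dynamics vary only `u` through `du`), though the implementation keeps
them equal rather than hard-coding it.

`instantaneous_linearization()` freezes the depression state along a
trajectory and analyzes the static network with those weights. Although
the depressed network is nonlinear, the frozen systems predict its
behavior well: with `du = -0.03` the trajectory crosses into the
delta-band instability region and the nonlinear simulation starts
oscillating within tens of milliseconds of the crossing; with
`du = +0.03` every frozen system stays stable and is several times
slower than its balanced (`du = 0`) counterpart at the same time point.
One subtlety of the true frozen systems: because the GABA weights do
not depress while the excitatory strength `We` shrinks, the frozen
networks actually get somewhat *faster* over the course of a pulse even
for positive `du` — the loss of recurrent positive feedback outweighs
the NMDA surplus. The slowing relative to balance is a between-`du`
comparison, not a within-trajectory trend. Very strong depression
(`u > 0.35`, `tau_r > 1.5 s`) damps the initial transient and needs
larger `|du|` for the same effect; no special-casing is applied — it
emerges from the same equations.

## The spiking network

`simulate_lif()` runs a network of leaky integrate-and-fire neurons
(3,200 excitatory, 800 inhibitory, connection probability 0.2) with
exponential AMPA/NMDA/GABA synapses, implemented in C++ for speed. Four
modeling choices deserve explanation, because the rate-model
parameters do not transfer to a spiking implementation without them.

* **Synaptic jump normalization.** A presynaptic spike increments the
  corresponding activation by `1/tau` of its receptor, so that each
  activation is an estimate of the presynaptic rate in Hz and the drive
  `J S` has the same meaning as in the rate model: `w` and `k` keep
  their quantitative roles. Under the alternative unit-jump convention
  the recurrent drive of the canonical `w = 5` network is two orders of
  magnitude too weak to produce any collective dynamics; the two
  conventions differ only by a rescaling of `w`, and this one keeps the
  printed numbers meaningful.
* **Background input.** Each neuron receives one merged Poisson stream
  (1,000 sources) of instantaneous voltage kicks of 0.2 mV. Two
  calibrations were necessary to obtain a functioning network. First,
  per-source rates of about 1 Hz elevate the membrane by only ~4 mV
  against the 20 mV gap between rest (-60 mV) and threshold (-40 mV),
  leaving the network provably silent; the package defaults use
  4.2/4.0 Hz (preserving the 1.05:1 excitatory:inhibitory ratio, which
  exists to equalize baseline rates), putting the membrane in a
  fluctuation-driven regime with a baseline of a few Hz. Second,
  because a voltage kick's steady-state elevation scales with the
  membrane time constant, inhibitory neurons (10 ms) would receive half
  the mean drive of excitatory ones (20 ms); inhibitory kicks are
  scaled by `tau_e/tau_i` so both populations see the same mean
  background drive, matching the stated intent of equal baseline rates.
* **Initial conditions.** Membrane voltages start uniformly distributed
  between rest and threshold (seeded). Identical initial voltages
  synchronize the whole population artificially and every reset
  re-synchronizes it, producing pathological global bursting.
* **Refractory periods.** Excitatory neurons have a 4 ms and
  (fast-spiking) inhibitory neurons a 1 ms absolute refractory period.
  Without one, a sufficiently strong fluctuation tips the `k < 1`
  network into a saturated state in which every neuron fires at `1/dt`;
  that state is absorbing because both populations saturate at the
  same rate, leaving net positive drive. With the shorter inhibitory
  refractory period, inhibition saturates at a higher rate than
  excitation during extreme excursions, so bursts self-terminate and
  the runaway state disappears. A runaway guard still monitors the
  population rate and flags (never truncates) pathological runs.

The spiking network reproduces the rate model's phenomenology
qualitatively, at larger `|dq|`: step responses slow down as `dq`
increases, and delta-band power grows as `dq` decreases toward the
AMPA-dominated instability. With per-synapse depression
(`simulate_lif_std()`), every connection carries an AMPA and an NMDA
synapse at half weight (exactly `q = 0.5`); depression efficacies are
tracked per presynaptic neuron (all its synapses see the same spike
train) with the `du` sign reversed on IE projections, each spike
transmitting with efficacy `x` before depressing it to `x(1-u)` — the
event-driven limit of the continuous usage term, whose regular-train
fixed point `std_event_train()` exposes in closed form.

### The frequency-response statistic

A neuron cannot observe the network's pole diagram, but it does receive
a sample of the network output: its recurrent glutamatergic input.
`neuron_frequency_response()` takes a 4 s window of that input
per neuron, removes the mean, and computes the DFT magnitude;
`band_area()` integrates it over the delta band (0.5-5.5 Hz) and
subtracts the same neuron's balanced-network (`dq = 0`) baseline. As
the network approaches the AMPA-dominated instability this area grows
steeply and monotonically — information sufficient, in principle, for a
local homeostatic controller to steer `dq` away from the seizure-prone
boundary. The protocol (`lif_delta_band_protocol()`) uses a 2 mV
smoothed step, 4 s settling, a 4 s window and runs averaged across
seeds.

## What the tests show — and what they do not

The simulations here are the study conditions themselves: parameter
sets printed in the source material plus internally generated stimuli.
There is no external data, so passing tests demonstrate internal
consistency (simulators agree with eigenanalysis; statistics behave as
the theory predicts under the model's own assumptions), not fit to
recordings. Features of real cortex deliberately absent: voltage
dependence of NMDA receptors, conductance-based synapses, synaptic
delays, heterogeneous cell parameters, and any biophysical
implementation of the homeostatic controller (only its information
source is computed). The delta-band trend is assessed on a
1,000-neuron network (800 excitatory, 200 inhibitory) with 40 recorded
neurons and 10 seeds per point, sizes chosen to keep a full analysis
run in the minutes range; the effect is large (the band area roughly
triples per -0.05 step of `dq`) and does not depend delicately on
network size, though the tipping boundaries do shift with size because
unitary synaptic weights scale as `1/(N p)`.

One further honesty note: the published rise time "approximately
5 seconds" at `dq = 0.1` computes to 3.97 s here (and 3.90 s via
`ln(9) tau_n`, 3.89 s with a smoothed step) — every reading of the
definition lands near 4 s, and the package reports the computed value
rather than tuning toward the rounder one.

## Worked example

```{r example, eval = FALSE}
p <- network_params(w = 30, k = 1.2, q = 0.3, dq = 0.05)
sys <- build_linear_system(p, "full")
stability_report(sys)      # stable, non-oscillatory, tau_n ~ 1 s
rise_time(sys)             # ~2.2 s

# where does the delta instability sit, and at what frequency?
find_imag_axis_crossing(p, "full", "decreasing_dq")[c("dq", "frequency_hz")]

# simulate the smoothed-step protocol and write the trajectory
traj <- simulate_full(p, make_input("step", 5, smoothing_sigma = 0.1),
                      duration = 3, dt = 1e-4)
write_trajectory(traj, "trajectory.csv")
```
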
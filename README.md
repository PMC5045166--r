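# eibalance

Simulation and stability analysis of balanced excitatory–inhibitory
cortical network models whose excitatory projections mix fast (AMPA)
and slow (NMDA) currents.

## The scientific problem

Recurrent cortical circuits keep excitation and inhibition balanced:
the classical stability requirement is that strength-weighted negative
feedback dominate positive feedback,

```
Jei (Jie_ampa + Jie_nmda) - Jii (Jee_ampa + Jee_nmda) > 0.
```

Because excitatory currents have two components with very different
kinetics, a *second* condition is required — the temporal balance
condition — in which each AMPA strength is weighted by the NMDA decay
time and vice versa:

```
Jei (Jie_ampa τ_nmda + Jie_nmda τ_ampa) - Jii (Jee_ampa τ_nmda + Jee_nmda τ_ampa) > 0.
```

Under the package's `(w, k, q, dq)` parameterization — base strength
`w`, inhibitory ratio `k`, NMDA fraction `q`, and an NMDA-fraction
shift `dq` applied to the EE projection only — the first condition
holds with equality by construction and the second collapses to
`k w² dq (τ_nmda − τ_ampa)`. The single parameter `dq` then spans the
network's whole behavioral repertoire: an AMPA-dominated oscillatory
instability in the **delta band** (~2 Hz) for small negative `dq`,
fast responses near critical damping, response times growing from tens
of milliseconds to seconds as `dq` increases, and a **gamma-band**
(~60 Hz) instability slightly below `dq = 0.15`. Networks that respond
fast necessarily sit at the edge of the delta instability — a possible
origin of cortical delta rhythms and absence seizures.

The package provides, for this model family:

* the parameterization with both balance diagnostics (`network_params`,
  `make_weights`, `balance_lhs`, `temporal_balance_lhs`);
* deterministic RK4 simulators for the full two-population network,
  the reduced one-population network, and the damped-spring
  approximation with `ω₀ = 1/√(τ_e τ_nmda)` (`simulate_full`,
  `simulate_reduced`, `simulate_spring`);
* a linear-analysis toolkit: exact poles, stability verdicts, network
  time constants, 10–90% rise times, transfer-function magnitudes,
  imaginary-axis crossings, critical damping points and parameter-sweep
  maps (`build_linear_system`, `stability_report`, `rise_time`,
  `transfer_magnitude`, `find_imag_axis_crossing`,
  `find_critical_damping`, `sweep_map`);
* Tsodyks–Markram short-term depression with receptor-specific usage
  rates, turning depression into a time-varying `dq`
  (`simulate_rate_std`, `instantaneous_linearization`);
* a C++-backed leaky integrate-and-fire network (AMPA/NMDA/GABA
  exponential synapses, Poisson background, optional per-synapse
  depression) and the per-neuron frequency-response statistic proposed
  as the information source for homeostatic control of the AMPA/NMDA
  ratio (`simulate_lif`, `neuron_frequency_response`, `band_area`,
  `lif_delta_band_protocol`).

## Worked example

```r
library(eibalance)

p <- network_params(w = 30, k = 1.2, q = 0.3, dq = 0.05)
stability_report(build_linear_system(p, "full"))
#> stable, non-oscillatory
#> tau_n = 1.017 s
#> dominant pole: -0.983436+0i 1/s

# the delta-band instability of the canonical network:
cr <- find_imag_axis_crossing(network_params(30, 1.2, 0.3),
                              "full", "decreasing_dq")
round(c(dq = cr$dq, freq_hz = cr$frequency_hz), 4)
#>      dq freq_hz
#> -0.0177  1.8497

# natural frequency of the spring approximation:
natural_frequency(0.02, 0.1)$hz
#> [1] 3.558813
```

The first result says the NMDA-shifted network is stable with a
network time constant of about a second (slow integration); the second
locates the edge of stability at `dq ≈ -0.018` with a resonance at
1.85 Hz — inside the delta band; the third is the undamped oscillation
frequency of the spring reduction, again delta-range, which is why
fast balanced networks sit next to a delta instability specifically.

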
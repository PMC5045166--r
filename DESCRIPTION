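Package: eibalance
Title: Balanced Excitatory-Inhibitory Network Dynamics and the Temporal
    Balance Condition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and linear stability analysis of rate-based and
    spiking (leaky integrate-and-fire) balanced excitatory-inhibitory
    cortical network models with mixed fast (AMPA) and slow (NMDA)
    glutamatergic currents. Provides the (w, k, q, dq) synaptic
    parameterization with its balance and temporal-balance stability
    diagnostics, a damped-harmonic-oscillator reduction, pole analysis
    with rise times and oscillatory-instability boundaries (delta and
    gamma bands), Tsodyks-Markram short-term depression with
    instantaneous linearization, and a per-neuron frequency-response
    statistic suitable as an information source for homeostatic control
    of the AMPA/NMDA ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
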
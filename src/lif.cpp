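#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Leaky integrate-and-fire network with exponential AMPA/NMDA/GABA
// synapses, merged-Poisson background kicks, and optional per-presynaptic
// short-term depression (usage-rate split du, sign reversed on the IE
// projections).
//
// Connectivity is CSR by source: targets[offsets[s] .. offsets[s+1]-1]
// are the 0-based postsynaptic indices of source s. Neurons 0..n_e-1 are
// excitatory, n_e..n_e+n_i-1 inhibitory.
//
// Per-neuron aggregated synaptic drives (already weighted, in mV):
// g_ampa, g_nmda from excitatory sources, g_gaba from inhibitory ones.
// A presynaptic spike increments the target's drive by J (unit jump in
// the underlying activation). Membrane update is exponential Euler with
// the total drive held constant over the step; background events are
// instantaneous voltage kicks. Uses R's RNG, so seeding happens in R.
//
// [[Rcpp::export]]
List lif_simulate_cpp(IntegerVector targets, IntegerVector offsets,
                      int n_e, int n_i,
                      double j_ee_ampa, double j_ee_nmda,
                      double j_ie_ampa, double j_ie_nmda,
                      double j_ei, double j_ii,
                      double tau_e, double tau_i,
                      double tau_ampa, double tau_nmda, double tau_gaba,
                      double e_l, double v_thresh, double v_reset,
                      double bg_rate_e, double bg_rate_i,
                      double bg_event_e, double bg_event_i,
                      NumericVector input, double dt,
                      bool use_std, double u, double du, double tau_r,
                      IntegerVector record_ids, int trace_every,
                      double rate_cap, NumericVector v_init,
                      double t_ref_e, double t_ref_i) {
  const int n = n_e + n_i;
  const int n_steps = input.size();
  std::vector<double> v(v_init.begin(), v_init.end()),
      ga(n, 0.0), gn(n, 0.0), gg(n, 0.0);
  // refractory handling: voltage clamped at reset until ref_until[m]
  const int ref_steps_e = (int)std::round(t_ref_e / dt);
  const int ref_steps_i = (int)std::round(t_ref_i / dt);
  std::vector<int> ref_until(n, 0);
  const double da = std::exp(-dt / tau_ampa);
  const double dn = std::exp(-dt / tau_nmda);
  const double dg = std::exp(-dt / tau_gaba);
  const double de = std::exp(-dt / tau_e);
  const double di = std::exp(-dt / tau_i);
  const double mu_e = bg_rate_e * dt, mu_i = bg_rate_i * dt;

  // STD state per excitatory source: efficacies for the four projection
  // classes (EE/IE x AMPA/NMDA) plus the time of the last update.
  std::vector<double> x_ee_a, x_ee_n, x_ie_a, x_ie_n, x_last;
  // positive du depresses EE AMPA harder (raising the effective NMDA
  // fraction); the sign of du is reversed on the IE projections
  const double u_ee_a = u + du, u_ee_n = u - du;
  const double u_ie_a = u - du, u_ie_n = u + du;
  if (use_std) {
    x_ee_a.assign(n_e, 1.0); x_ee_n.assign(n_e, 1.0);
    x_ie_a.assign(n_e, 1.0); x_ie_n.assign(n_e, 1.0);
    x_last.assign(n_e, 0.0);
  }

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 16);
  spike_t.reserve(1 << 16);

  const int n_rec = record_ids.size();
  const int n_samp = (trace_every > 0) ? (n_steps / trace_every + 1) : 0;
  NumericMatrix traces(n_samp > 0 ? n_samp : 1, n_rec);
  int samp_row = 0;

  // Runaway guard: excitatory population rate in 100 ms windows.
  const int guard_steps = std::max(1, (int)std::round(0.1 / dt));
  int guard_count = 0;
  bool runaway = false;

  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    const double inp = input[k];
    for (int m = 0; m < n; ++m) {
      ga[m] *= da; gn[m] *= dn; gg[m] *= dg;
      const bool exc = m < n_e;
      if (k < ref_until[m]) { v[m] = v_reset; continue; }
      const double x = ga[m] + gn[m] - gg[m] + (exc ? inp : 0.0);
      const double dm = exc ? de : di;
      v[m] = x + e_l + (v[m] - e_l - x) * dm;
    }
    // background: one merged Poisson draw per population per step,
    // events assigned to neurons uniformly (equivalent to independent
    // per-neuron streams, far fewer RNG calls)
    {
      const int tot_e = (int)R::rpois(mu_e * n_e);
      for (int j = 0; j < tot_e; ++j)
        v[(int)(R::unif_rand() * n_e)] += bg_event_e;
      const int tot_i = (int)R::rpois(mu_i * n_i);
      for (int j = 0; j < tot_i; ++j)
        v[n_e + (int)(R::unif_rand() * n_i)] += bg_event_i;
    }
    for (int s = 0; s < n; ++s) {
      if (v[s] < v_thresh) continue;
      v[s] = v_reset;
      ref_until[s] = k + 1 + (s < n_e ? ref_steps_e : ref_steps_i);
      spike_id.push_back(s);
      spike_t.push_back(t);
      if (s < n_e) ++guard_count;
      double wee_a = j_ee_ampa, wee_n = j_ee_nmda;
      double wie_a = j_ie_ampa, wie_n = j_ie_nmda;
      const bool src_exc = s < n_e;
      if (use_std && src_exc) {
        const double rec = std::exp(-(t - x_last[s]) / tau_r);
        x_ee_a[s] = 1.0 - (1.0 - x_ee_a[s]) * rec;
        x_ee_n[s] = 1.0 - (1.0 - x_ee_n[s]) * rec;
        x_ie_a[s] = 1.0 - (1.0 - x_ie_a[s]) * rec;
        x_ie_n[s] = 1.0 - (1.0 - x_ie_n[s]) * rec;
        x_last[s] = t;
        wee_a *= x_ee_a[s]; wee_n *= x_ee_n[s];
        wie_a *= x_ie_a[s]; wie_n *= x_ie_n[s];
      }
      for (int e = offsets[s]; e < offsets[s + 1]; ++e) {
        const int tgt = targets[e];
        if (src_exc) {
          if (tgt < n_e) { ga[tgt] += wee_a; gn[tgt] += wee_n; }
          else           { ga[tgt] += wie_a; gn[tgt] += wie_n; }
        } else {
          gg[tgt] += (tgt < n_e) ? j_ei : j_ii;
        }
      }
      if (use_std && src_exc) {  // transmit with x, then depress
        x_ee_a[s] *= (1.0 - u_ee_a);
        x_ee_n[s] *= (1.0 - u_ee_n);
        x_ie_a[s] *= (1.0 - u_ie_a);
        x_ie_n[s] *= (1.0 - u_ie_n);
      }
    }
    if (trace_every > 0 && k % trace_every == 0) {
      for (int r = 0; r < n_rec; ++r) {
        const int id = record_ids[r];
        traces(samp_row, r) = ga[id] + gn[id];
      }
      ++samp_row;
    }
    if ((k + 1) % guard_steps == 0) {
      const double rate = guard_count / (0.1 * n_e);
      if (rate > rate_cap) runaway = true;
      guard_count = 0;
    }
  }

  return List::create(_["spike_id"] = wrap(spike_id),
                      _["spike_time"] = wrap(spike_t),
                      _["traces"] = traces,
                      _["n_trace_samples"] = samp_row,
                      _["runaway"] = runaway);
}
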
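// Fixed-step forward-Euler engine for networks of Izhikevich neurons with
// conductance-based chemical synapses and gap junctions.
//
// Update order within a step (time t -> t + dt):
//   1. synaptic + applied currents from the current (pre-update) states
//   2. Euler update of all (v, u), using the pre-reset v for both equations
//   3. gate decay (one Euler step of ds/dt = -s/tau)
//   4. reset check: v >= v_p  ->  v <- c, u <- u + d; spike time = t + dt
//   5. gate increment (+1 per presynaptic spike registered this step)
// Zero axonal delay: a spike in step k first drives its postsynaptic targets
// in step k + 1. Electrical current is computed from instantaneous pre-reset
// membrane potentials every step, which is what transmits spikelets.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List sim_engine_cpp(NumericVector C, NumericVector vr, NumericVector vt,
                    NumericVector vp, NumericVector kk, NumericVector aa,
                    NumericVector bb, NumericVector cc, NumericVector dd,
                    NumericVector vb, LogicalVector is_fs,
                    NumericVector I_hold,
                    IntegerVector syn_pre, IntegerVector syn_post,
                    NumericVector syn_G, NumericVector syn_E,
                    NumericVector syn_tau,
                    IntegerVector el_a, IntegerVector el_b,
                    NumericVector el_G,
                    IntegerVector pls_tgt, NumericVector pls_I0,
                    NumericVector pls_on, NumericVector pls_dur,
                    double dt, double duration,
                    NumericVector v_init, NumericVector u_init,
                    bool record_v) {
  const int n = C.size();
  const int n_syn = syn_pre.size();
  const int n_el = el_a.size();
  const int n_pls = pls_tgt.size();
  const int n_steps = (int)std::lround(duration / dt);

  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> u(u_init.begin(), u_init.end());
  std::vector<double> s(n_syn, 0.0);
  std::vector<double> Isyn(n), Iapp(n);
  std::vector<int> n_spk(n, 0);

  std::vector<int> spk_neuron;
  std::vector<double> spk_time;

  NumericMatrix vrec(record_v ? n_steps + 1 : 0, record_v ? n : 0);
  if (record_v)
    for (int i = 0; i < n; ++i) vrec(0, i) = v[i];

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // 1. currents from current states
    for (int i = 0; i < n; ++i) { Isyn[i] = 0.0; Iapp[i] = I_hold[i]; }
    for (int j = 0; j < n_syn; ++j) {
      const int post = syn_post[j];
      Isyn[post] += syn_G[j] * s[j] * (syn_E[j] - v[post]);
    }
    for (int j = 0; j < n_el; ++j) {
      const double cur = el_G[j] * (v[el_a[j]] - v[el_b[j]]);
      Isyn[el_b[j]] += cur;
      Isyn[el_a[j]] -= cur;
    }
    for (int j = 0; j < n_pls; ++j) {
      if (t >= pls_on[j] && t < pls_on[j] + pls_dur[j])
        Iapp[pls_tgt[j]] += pls_I0[j];
    }

    // 2. Euler update of (v, u) with pre-reset v
    for (int i = 0; i < n; ++i) {
      const double vi = v[i];
      const double dv = (kk[i] * (vi - vr[i]) * (vi - vt[i]) - u[i]
                         + Iapp[i] + Isyn[i]) / C[i];
      double fu;
      if (is_fs[i]) {
        const double U = (vi < vb[i]) ? 0.0
          : bb[i] * (vi - vb[i]) * (vi - vb[i]) * (vi - vb[i]);
        fu = U - u[i];
      } else {
        fu = bb[i] * (vi - vr[i]) - u[i];
      }
      v[i] = vi + dt * dv;
      u[i] += dt * aa[i] * fu;
    }

    // 3. gate decay
    for (int j = 0; j < n_syn; ++j) s[j] -= dt * s[j] / syn_tau[j];

    // 4. resets; spike recorded at the end of the step
    std::fill(n_spk.begin(), n_spk.end(), 0);
    bool any_spike = false;
    for (int i = 0; i < n; ++i) {
      if (v[i] >= vp[i]) {
        v[i] = cc[i];
        u[i] += dd[i];
        n_spk[i] = 1;
        any_spike = true;
        spk_neuron.push_back(i + 1);
        spk_time.push_back((step + 1) * dt);
      } else if (v[i] > 200.0 || v[i] < -200.0) {
        stop("numerical divergence: |v| exceeded 200 mV at t = %f ms (neuron %d)",
             t, i + 1);
      }
    }

    // 5. gate increments
    if (any_spike)
      for (int j = 0; j < n_syn; ++j) s[j] += n_spk[syn_pre[j]];

    if (record_v)
      for (int i = 0; i < n; ++i) vrec(step + 1, i) = v[i];
  }

  List out = List::create(
    _["spike_neuron"] = wrap(spk_neuron),
    _["spike_time"] = wrap(spk_time),
    _["v_final"] = wrap(v),
    _["u_final"] = wrap(u));
  if (record_v) out["v"] = vrec;
  return out;
}
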
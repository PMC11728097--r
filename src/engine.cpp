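// Spiking-network engine: 16-compartment leaky integrate-and-fire neurons
// driven by shift-register AMPA/NMDA/GABA synapses with voltage-gated NMDA
// (Mg2+ block) and LTP. Mirrors the pure-R synapse/neuron reference
// implementations; all randomness (membrane noise) is generated in R and
// passed in, so a run is a deterministic function of its inputs.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List engine_run(IntegerMatrix conn_i,   // src_kind, src_idx, tgt, comp, kind, enabled
                NumericMatrix conn_d,   // w_e, w_m, power, ca_mem, clog
                IntegerMatrix ext,      // n_lines x n_steps external spikes (0/1)
                NumericMatrix noise,    // n_neurons x n_steps somatic noise (mV)
                NumericVector tau_m,    // per neuron
                NumericVector refractory, // per neuron, ms
                List pars) {
  const int n_conn = conn_i.nrow();
  const int n_neur = tau_m.size();
  const int n_steps = as<int>(pars["n_steps"]);
  const double dt = as<double>(pars["dt"]);
  const int substeps = as<int>(pars["substeps"]);
  const double lambda = as<double>(pars["axial"]);
  const double rest = as<double>(pars["rest_potential"]);
  const double thresh = as<double>(pars["spike_threshold"]);
  const double kappa = as<double>(pars["drive_gain"]);
  const double tau_dend = as<double>(pars["tau_dend"]);
  const int L = as<int>(pars["register_length"]);
  const double tau_ampa = as<double>(pars["tau_ampa"]);
  const double tau_nmda = as<double>(pars["tau_nmda"]);
  const double tau_gaba = as<double>(pars["tau_gaba"]);
  const int ltp_dur = as<int>(pars["ltp_duration"]);
  const double ltp_gain = as<double>(pars["ltp_gain"]);
  const int n_comp = 16;

  // decay kernels by spike age (steps)
  std::vector<double> kerA(L), kerG(L), kerM(L);
  for (int a = 0; a < L; ++a) {
    kerA[a] = std::exp(-a * dt / tau_ampa);
    kerG[a] = std::exp(-a * dt / tau_gaba);
    kerM[a] = std::exp(-a * dt / tau_nmda);
  }

  // synapse state: circular raw-amplitude buffers + LTP bookkeeping
  std::vector<double> ampE((size_t)n_conn * L, 0.0);
  std::vector<double> ampM((size_t)n_conn * L, 0.0);
  std::vector<int> ltp_timer(n_conn, 0);
  std::vector<double> gain(n_conn, 1.0);

  // neuron state
  std::vector<double> v((size_t)n_neur * n_comp, rest);
  std::vector<double> refr(n_neur, 0.0);
  std::vector<int> spiked_prev(n_neur, 0), spiked_now(n_neur, 0);
  std::vector<double> drive((size_t)n_neur * n_comp, 0.0);

  // compartment neighbors: 1=soma(0), axon(1), branches 2..8 and 9..15
  std::vector<std::vector<int>> nb(n_comp);
  auto edge = [&](int a, int b) { nb[a].push_back(b); nb[b].push_back(a); };
  edge(0, 1); edge(0, 2);
  for (int c = 2; c < 8; ++c) edge(c, c + 1);
  edge(0, 9);
  for (int c = 9; c < 15; ++c) edge(c, c + 1);

  std::vector<int> out_neuron;
  std::vector<int> out_step;
  const double h = dt / substeps;

  for (int t = 0; t < n_steps; ++t) {
    std::fill(drive.begin(), drive.end(), 0.0);
    const int slot = t % L;
    const int ages = std::min(t + 1, L);

    for (int c = 0; c < n_conn; ++c) {
      if (!conn_i(c, 5)) continue;  // disabled: transmits nothing
      const int src_kind = conn_i(c, 0);
      const int src = conn_i(c, 1);
      bool spike = src_kind == 0 ? ext(src, t) != 0 : spiked_prev[src] != 0;
      double *aE = &ampE[(size_t)c * L];
      double *aM = &ampM[(size_t)c * L];
      aE[slot] = spike ? conn_d(c, 0) * gain[c] : 0.0;
      aM[slot] = spike ? conn_d(c, 1) * gain[c] : 0.0;

      const bool inhib = conn_i(c, 4) == 1;
      double sumE = 0.0, sumM = 0.0;
      for (int a = 0; a < ages; ++a) {
        const int j = slot - a >= 0 ? slot - a : slot - a + L;
        sumE += aE[j] * (inhib ? kerG[a] : kerA[a]);
        if (!inhib) sumM += aM[j] * kerM[a];
      }

      const double power = conn_d(c, 2);
      double s;
      if (inhib) {
        s = rest + power * conn_d(c, 4) * sumE;  // clog on inhibition
      } else {
        s = rest + power * sumE;
        // NMDA machinery (gating, LTP) only on NMDA-bearing synapses
        if (conn_d(c, 1) != 0.0) {
          if (s > conn_d(c, 3)) {        // Mg2+ block removed
            s += sumM;
            ltp_timer[c] = ltp_dur;
            gain[c] = ltp_gain;
          } else if (ltp_timer[c] > 0) {
            if (--ltp_timer[c] == 0) gain[c] = 1.0;
          }
        }
      }
      drive[(size_t)conn_i(c, 2) * n_comp + conn_i(c, 3)] += kappa * (s - rest);
    }

    for (int n = 0; n < n_neur; ++n) {
      double *vn = &v[(size_t)n * n_comp];
      const double *dn = &drive[(size_t)n * n_comp];
      for (int s = 0; s < substeps; ++s) {
        double vnew[16];
        for (int c = 0; c < n_comp; ++c) {
          double ax = 0.0;
          for (int k : nb[c]) ax += vn[k] - vn[c];
          const double leak = (rest - vn[c]) / (c == 0 ? tau_m[n] : tau_dend);
          vnew[c] = vn[c] + h * (leak + lambda * ax + dn[c]);
        }
        for (int c = 0; c < n_comp; ++c) vn[c] = vnew[c];
      }
      vn[0] += noise(n, t);
      spiked_now[n] = 0;
      if (refr[n] > 0) {
        refr[n] -= dt;
        vn[0] = rest; vn[1] = rest;
      } else if (vn[0] >= thresh) {
        spiked_now[n] = 1;
        vn[0] = rest; vn[1] = rest;
        refr[n] = refractory[n];
        out_neuron.push_back(n + 1);
        out_step.push_back(t);
      }
    }
    std::swap(spiked_prev, spiked_now);
  }

  return List::create(_["neuron"] = wrap(out_neuron),
                      _["step"] = wrap(out_step));
}
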
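#include <Rcpp.h>
using namespace Rcpp;

// Spiking LIF network with action-potential template insertion and
// per-spike postsynaptic-current kernel accumulation.
//
// Units: mV, nA, nF, MOhm; dt in ms. Forward Euler:
//   V += dt/Cm * ((V0 - V)/Rm + I_ext + I_syn)
// A threshold crossing outside an active template inserts the template into
// the voltage trace (absolute refractory period) and adds the PSC kernel to
// the unit's output-current ring buffer; synaptic input to unit i is
// sum_j M(j,i) * I_out_j(t). External stimulus spikes feed a separate
// per-unit buffer through the same unit kernel.
//
// [[Rcpp::export]]
List simulate_lif_cpp(NumericMatrix M,            // N x N, M(j,i): j -> i
                      IntegerMatrix ext_spikes,   // n_steps x n_stim counts
                      IntegerVector stim_units,   // 1-based unit index per col
                      NumericVector i_ext,        // length N constant drive (nA)
                      NumericVector cm,           // per unit, nF
                      NumericVector rm,           // per unit, MOhm
                      double v0, double vthr,
                      NumericVector ap_tpl,       // mV
                      NumericVector psc,          // nA (unit kernel)
                      double dt_ms, int n_steps,
                      bool record_v, int record_every) {
  const int N = M.nrow();
  if (M.ncol() != N) stop("connectivity matrix must be square");
  for (int i = 0; i < N * N; ++i)
    if (!R_finite(M[i])) stop("non-finite connectivity matrix");
  if (cm.size() != N || rm.size() != N || i_ext.size() != N)
    stop("parameter vector length mismatch");
  const int K = psc.size();
  const int L = ap_tpl.size();
  const int n_stim = ext_spikes.ncol();
  if (n_stim != stim_units.size()) stop("stim_units length mismatch");
  if (n_stim > 0 && ext_spikes.nrow() < n_steps)
    stop("stimulus shorter than simulation");

  // edge list of nonzero entries for sparse synaptic accumulation
  std::vector<int> e_pre, e_post;
  std::vector<double> e_w;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      if (M(j, i) != 0.0) {
        e_pre.push_back(j); e_post.push_back(i); e_w.push_back(M(j, i));
      }
  const int n_edges = (int)e_pre.size();

  std::vector<double> out_buf((size_t)N * K, 0.0); // recurrent PSC currents
  std::vector<double> ext_buf((size_t)N * K, 0.0); // stimulus PSC currents
  std::vector<double> V(N, v0);
  std::vector<int> tmpl_pos(N, -1);
  std::vector<double> i_syn(N);
  std::vector<std::vector<int>> spikes(N);
  int head = 0;

  int n_rec = record_v ? (n_steps + record_every - 1) / record_every : 0;
  NumericMatrix v_trace(record_v ? n_rec : 0, record_v ? N : 0);

  for (int s = 0; s < n_steps; ++s) {
    // synaptic currents from ring buffers at the current head
    for (int i = 0; i < N; ++i) i_syn[i] = 0.0;
    for (int e = 0; e < n_edges; ++e)
      i_syn[e_post[e]] += e_w[e] * out_buf[(size_t)e_pre[e] * K + head];

    // external stimulus spikes arriving this step
    for (int c = 0; c < n_stim; ++c) {
      int cnt = ext_spikes(s, c);
      if (cnt > 0) {
        double *buf = &ext_buf[(size_t)(stim_units[c] - 1) * K];
        for (int k = 0; k < K; ++k)
          buf[(head + k) % K] += cnt * psc[k];
      }
    }

    for (int i = 0; i < N; ++i) {
      if (tmpl_pos[i] >= 0) { // template active: voltage is stereotyped
        V[i] = ap_tpl[tmpl_pos[i]];
        if (++tmpl_pos[i] >= L) tmpl_pos[i] = -1;
      } else {
        double I = i_ext[i] + i_syn[i] + ext_buf[(size_t)i * K + head];
        V[i] += dt_ms / cm[i] * ((v0 - V[i]) / rm[i] + I);
        if (V[i] >= vthr) {
          spikes[i].push_back(s);
          V[i] = ap_tpl[0];
          tmpl_pos[i] = 1;
          double *buf = &out_buf[(size_t)i * K];
          for (int k = 0; k < K; ++k)
            buf[(head + k) % K] += psc[k];
        }
      }
      if (record_v && s % record_every == 0)
        v_trace(s / record_every, i) = V[i];
    }

    // expire the consumed buffer slot and advance
    for (int i = 0; i < N; ++i) {
      out_buf[(size_t)i * K + head] = 0.0;
      ext_buf[(size_t)i * K + head] = 0.0;
    }
    head = (head + 1) % K;
  }

  List sp(N);
  for (int i = 0; i < N; ++i) sp[i] = wrap(spikes[i]);
  List res = List::create(_["spike_steps"] = sp, _["n_steps"] = n_steps);
  if (record_v) res["v"] = v_trace;
  return res;
}
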
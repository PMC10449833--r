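// Time-stepped simulation core for conductance-based AdEx networks.
//
// Forward Euler on V and w at a fixed step dt; synaptic conductances decay
// by the exact per-step exponential factor, which removes the stiffness of
// the fastest synaptic time constant. Recurrent spikes are delivered through
// a ring buffer after a uniform conduction delay; external drive is one
// equivalent Poisson process per neuron realized by exponential
// inter-arrival skipping. Fully deterministic given the seed.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Column layout of the per-population parameter matrix (see R wrapper).
enum ParCol {
  P_CM = 0, P_EL, P_GL, P_VTH, P_VR, P_DT, P_A, P_B, P_TAUW, P_TR,
  P_EE, P_EI, P_TAUE, P_TAUI, P_IE, P_ADAPT, P_NCOL
};

// [[Rcpp::export]]
List sim_network_cpp(IntegerVector pop_id,        // 0-based population per neuron
                     NumericMatrix pars,          // one row per population
                     IntegerVector edge_src,      // 0-based
                     IntegerVector edge_tgt,
                     NumericVector edge_w,        // nS
                     IntegerVector edge_inh,      // 1 = inhibitory synapse
                     double delay_ms,
                     NumericVector ext_rate0,     // per-neuron equivalent rate, Hz
                     NumericVector ext_rate1,
                     double onset_ms,
                     double duration_ms,
                     double dt,
                     double w_ext,                // nS
                     double seed) {
  const int N = pop_id.size();
  const int npop = pars.nrow();
  const int n_edges = edge_src.size();
  const int n_steps = (int)std::lround(duration_ms / dt);
  const int D = (int)std::lround(delay_ms / dt);
  if (std::fabs(D * dt - delay_ms) > 1e-9)
    stop("delay must be an integer multiple of dt");
  const int ring = D + 1;
  const int onset_step = (int)std::lround(onset_ms / dt);

  // per-population precomputation (plain arrays keep the hot loop cheap)
  std::vector<double> dec_e(npop), dec_i(npop), ceil_v(npop);
  std::vector<int> refr_steps(npop), has_adapt(npop);
  std::vector<double> cm(npop), el(npop), gl(npop), vth(npop), vr(npop),
      dT(npop), pa(npop), pb(npop), tauw(npop), ee(npop), eiv(npop), ie(npop);
  for (int p = 0; p < npop; ++p) {
    dec_e[p] = std::exp(-dt / pars(p, P_TAUE));
    dec_i[p] = std::exp(-dt / pars(p, P_TAUI));
    has_adapt[p] = (int)pars(p, P_ADAPT);
    ceil_v[p] = has_adapt[p] ? pars(p, P_VTH) + 5.0 * pars(p, P_DT)
                             : pars(p, P_VTH);
    refr_steps[p] = (int)std::lround(pars(p, P_TR) / dt);
    cm[p] = pars(p, P_CM); el[p] = pars(p, P_EL); gl[p] = pars(p, P_GL);
    vth[p] = pars(p, P_VTH); vr[p] = pars(p, P_VR); dT[p] = pars(p, P_DT);
    pa[p] = pars(p, P_A); pb[p] = pars(p, P_B); tauw[p] = pars(p, P_TAUW);
    ee[p] = pars(p, P_EE); eiv[p] = pars(p, P_EI); ie[p] = pars(p, P_IE);
  }

  // CSR adjacency by source
  std::vector<int> offs(N + 1, 0);
  for (int e = 0; e < n_edges; ++e) offs[edge_src[e] + 1]++;
  for (int i = 0; i < N; ++i) offs[i + 1] += offs[i];
  std::vector<int> adj_tgt(n_edges);
  std::vector<double> adj_w(n_edges);
  std::vector<char> adj_inh(n_edges);
  {
    std::vector<int> cur(offs.begin(), offs.end() - 1);
    for (int e = 0; e < n_edges; ++e) {
      int k = cur[edge_src[e]]++;
      adj_tgt[k] = edge_tgt[e];
      adj_w[k] = edge_w[e];
      adj_inh[k] = (char)edge_inh[e];
    }
  }

  // state
  std::vector<double> V(N), w(N, 0.0), ge(N, 0.0), gi(N, 0.0);
  std::vector<int> ref_until(N, -1);   // first step at which updates resume
  std::vector<int> pid(N);
  for (int i = 0; i < N; ++i) {
    pid[i] = pop_id[i];
    V[i] = el[pid[i]];
  }

  std::vector<double> buf_e((size_t)ring * N, 0.0), buf_i((size_t)ring * N, 0.0);

  // external drive: exponential inter-arrival skipping
  std::mt19937_64 rng((uint64_t)seed);
  std::exponential_distribution<double> edist(1.0);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> rate_ms(N), next_ext(N);
  for (int i = 0; i < N; ++i) {
    rate_ms[i] = ext_rate0[i] / 1000.0;
    next_ext[i] = rate_ms[i] > 0 ? edist(rng) / rate_ms[i] : INF;
  }

  std::vector<int> spk_id;
  std::vector<double> spk_t;
  std::vector<int> step_spikes;
  step_spikes.reserve(256);

  for (int s = 0; s < n_steps; ++s) {
    const double t1 = (s + 1) * dt;
    if (s == onset_step) {
      // rate switch: memoryless, so redraw the pending arrival from onset
      for (int i = 0; i < N; ++i) {
        rate_ms[i] = ext_rate1[i] / 1000.0;
        next_ext[i] = rate_ms[i] > 0 ? onset_ms + edist(rng) / rate_ms[i] : INF;
      }
    }
    const int slot = s % ring;
    step_spikes.clear();

    for (int i = 0; i < N; ++i) {
      const int p = pid[i];
      size_t bi = (size_t)slot * N + i;
      double gei = ge[i] * dec_e[p] + buf_e[bi];
      double gii = gi[i] * dec_i[p] + buf_i[bi];
      buf_e[bi] = 0.0;
      buf_i[bi] = 0.0;
      while (next_ext[i] < t1) {
        gei += w_ext;
        next_ext[i] += edist(rng) / rate_ms[i];
      }
      ge[i] = gei;
      gi[i] = gii;

      if (s < ref_until[i]) {
        // V clamped at reset; conductances (above) and w keep evolving
        V[i] = vr[p];
        if (has_adapt[p])
          w[i] += dt * (pa[p] * (vr[p] - el[p]) - w[i]) / tauw[p];
        continue;
      }
      double Vi = V[i], wi = w[i];
      double Iexp = 0.0, dw = 0.0;
      if (has_adapt[p]) {
        double arg = (Vi - vth[p]) / dT[p];
        if (arg > 20.0) arg = 20.0;   // overflow guard; detection resets first
        Iexp = gl[p] * dT[p] * std::exp(arg);
        dw = (pa[p] * (Vi - el[p]) - wi) / tauw[p];
      }
      const double dV = (-gl[p] * (Vi - el[p]) + Iexp
                         - gei * (Vi - ee[p])
                         - gii * (Vi - eiv[p])
                         - wi + ie[p]) / cm[p];
      Vi += dt * dV;
      wi += dt * dw;
      if (!std::isfinite(Vi) || !std::isfinite(wi))
        stop("non-finite state at t = %f ms (neuron %d)", t1, i + 1);
      if (Vi >= ceil_v[p]) {
        spk_id.push_back(i + 1);
        spk_t.push_back(t1);
        step_spikes.push_back(i);
        Vi = vr[p];
        if (has_adapt[p]) wi += pb[p];
        ref_until[i] = s + 1 + refr_steps[p];
      }
      V[i] = Vi;
      w[i] = wi;
    }

    // deliver this step's spikes after all reads: consumed at step s + D + 1
    if (!step_spikes.empty()) {
      const size_t wslot = (size_t)slot * N;
      for (int i : step_spikes) {
        for (int k = offs[i]; k < offs[i + 1]; ++k) {
          if (adj_inh[k]) buf_i[wslot + adj_tgt[k]] += adj_w[k];
          else            buf_e[wslot + adj_tgt[k]] += adj_w[k];
        }
      }
    }
  }

  return List::create(_["neuron_id"] = wrap(spk_id),
                      _["time_ms"] = wrap(spk_t));
}
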
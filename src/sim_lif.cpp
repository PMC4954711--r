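#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Event-loop integrator for an excitatory LIF network with short-term
// synaptic depression (effective/recovered/inactive resource fractions).
//
// Per-term exponential updates over a fixed step dt:
//   V    <- V e^{-dt/tau_m} + (1000 I_syn / g_l)(1 - e^{-dt/tau_m})
//   Isyn <- Isyn e^{-dt/tau_s}            (+ delta arrivals)
//   E    <- E e^{-dt/tau_inact}
//   R    <- (1-E) + (R - (1-E)) e^{-dt/tau_rec}   (E held over the step)
// The factor 1000 converts pA/pS (= volts) to mV, the unit of V_thr.
//
// Depression state is kept per presynaptic neuron: with homogeneous
// weights and shared (U, tau_inact, tau_rec) every synapse leaving j
// carries the same state, so E_ji = E_j exactly.
//
// A spike of j at time t schedules delivery at t + t_d; on arrival each
// postsynaptic target i with A_ji = 1 receives alpha_int * E_j(t + t_d)
// added to I_syn. External Poisson events are delivered with weight
// alpha_ext after the same delay. Threshold crossing resets V to 0 and
// clamps it (input ignored) for t_ref.
//
// Uses R's RNG so set.seed() on the R side controls reproducibility.

// [[Rcpp::export]]
List sim_lif_cpp(IntegerMatrix adj, double dt, double duration_ms,
                 double tau_m, double g_l, double V_thr, double t_ref,
                 double tau_s, double t_d, double alpha_int,
                 double alpha_ext, double ext_rate_hz,
                 double U, double tau_inact, double tau_rec,
                 bool record_state, int record_every) {
  const int n = adj.nrow();
  if (adj.ncol() != n) stop("adjacency matrix must be square");
  const long n_steps = (long)(duration_ms / dt + 0.5);
  const int d_steps = std::max(1, (int)(t_d / dt + 0.5));

  const double dec_V = std::exp(-dt / tau_m);
  const double dec_I = std::exp(-dt / tau_s);
  const double dec_E = std::exp(-dt / tau_inact);
  const double dec_R = std::exp(-dt / tau_rec);
  const double p_ext = ext_rate_hz * dt / 1000.0;  // rate in Hz, dt in ms

  std::vector<double> V(n, 0.0), Isyn(n, 0.0), E(n, 0.0), R(n, 1.0);
  std::vector<double> ref_until(n, -1.0);

  // delay ring: spiking presynaptic ids + per-neuron external event counts
  std::vector< std::vector<int> > ring_spk(d_steps);
  std::vector< std::vector<int> > ring_ext(d_steps, std::vector<int>(n, 0));

  // postsynaptic target lists
  std::vector< std::vector<int> > targets(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (adj(j, i) != 0) targets[j].push_back(i);

  std::vector< std::vector<double> > spikes(n), ext_times(n);

  long n_rec = record_state ? (n_steps / record_every + 1) : 0;
  NumericMatrix recV(record_state ? n_rec : 0, record_state ? n : 0);
  NumericMatrix recE(record_state ? n_rec : 0, record_state ? n : 0);
  NumericMatrix recI(record_state ? n_rec : 0, record_state ? n : 0);
  NumericMatrix recR(record_state ? n_rec : 0, record_state ? n : 0);
  NumericVector rec_t(record_state ? n_rec : 0);
  long rec_i = 0;
  if (record_state) { rec_t[0] = 0.0; rec_i = 1; }

  RNGScope scope;

  for (long step = 1; step <= n_steps; ++step) {
    const double t = step * dt;
    const int slot = (int)(step % d_steps);

    // 1. decay all states over dt (V driven by Isyn held over the step)
    for (int i = 0; i < n; ++i) {
      if (t < ref_until[i] - 0.5 * dt) {  // half-step tolerance: FP-safe

        V[i] = 0.0;
      } else {
        const double drive = 1000.0 * Isyn[i] / g_l;
        V[i] = V[i] * dec_V + drive * (1.0 - dec_V);
      }
      Isyn[i] *= dec_I;
      const double Enew = E[i] * dec_E;
      R[i] = (1.0 - Enew) + (R[i] - (1.0 - Enew)) * dec_R;
      E[i] = Enew;
    }

    // 2. deliver arrivals scheduled d_steps ago for this slot
    {
      std::vector<int> &spk = ring_spk[slot];
      for (size_t s = 0; s < spk.size(); ++s) {
        const int j = spk[s];
        const double amp = alpha_int * E[j];
        const std::vector<int> &tg = targets[j];
        for (size_t q = 0; q < tg.size(); ++q) Isyn[tg[q]] += amp;
      }
      spk.clear();
      std::vector<int> &ext = ring_ext[slot];
      for (int i = 0; i < n; ++i) {
        if (ext[i] > 0) { Isyn[i] += alpha_ext * ext[i]; ext[i] = 0; }
      }
    }

    // 3. draw external Poisson events, schedule after the delay
    if (p_ext > 0.0) {
      for (int i = 0; i < n; ++i) {
        if (unif_rand() < p_ext) {
          ring_ext[slot][i] += 1;  // slot reused: delivery in d_steps steps
          ext_times[i].push_back(t);
        }
      }
    }

    // 4. threshold crossings: reset, clamp, depression jump, schedule
    for (int i = 0; i < n; ++i) {
      if (V[i] >= V_thr && t >= ref_until[i] - 0.5 * dt) {
        spikes[i].push_back(t);
        V[i] = 0.0;
        ref_until[i] = t + t_ref;
        const double moved = U * R[i];  // fraction U of recovered pool
        E[i] += moved;
        R[i] -= moved;
        ring_spk[slot].push_back(i);
      }
    }

    if (record_state && (step % record_every == 0) && rec_i < n_rec) {
      for (int i = 0; i < n; ++i) {
        recV(rec_i, i) = V[i]; recE(rec_i, i) = E[i]; recR(rec_i, i) = R[i];
        recI(rec_i, i) = Isyn[i];
      }
      rec_t[rec_i] = t;
      ++rec_i;
    }

    if (step % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  List spk(n), ext(n);
  for (int i = 0; i < n; ++i) {
    spk[i] = NumericVector(spikes[i].begin(), spikes[i].end());
    ext[i] = NumericVector(ext_times[i].begin(), ext_times[i].end());
  }
  List out = List::create(_["spikes"] = spk, _["external"] = ext);
  if (record_state) {
    out["V"] = recV; out["E"] = recE; out["R"] = recR; out["Isyn"] = recI;
    out["times"] = rec_t;
  }
  return out;
}
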
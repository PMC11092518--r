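// Closed-loop spiking-network engine.
//
// Izhikevich neuron populations (9-parameter form, forward Euler with the
// voltage advanced in two half-steps per step) coupled by Tsodyks-Markram
// conductance synapses with event-driven exact-exponential state updates,
// fixed integral-step conduction delays, velocity-tuned conjunctive drive,
// Gaussian place-field drive and a decaying settle pulse. All state is
// double precision and the update order is fixed, so a run is bit-identical
// for identical inputs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pop {
  std::string name;
  int n;
  double C, k, vr, vt, a, b, vpeak, vreset, d;
  std::vector<double> v, u, I;
};

struct Group {
  int pre_pop, post_pop;
  // CSR over presynaptic neurons
  std::vector<int> row_ptr;     // size n_pre + 1
  std::vector<int> post;        // per edge
  std::vector<double> w, eu, ex, last_t;
  double g_fast, tau_d_fast, U, tau_u, tau_x, g_slow, tau_d_slow;
  bool inhib;
  double df_fast, df_slow;      // per-step decay factors
  std::vector<double> s_fast, s_slow;  // per postsynaptic neuron (nS)
};

inline double mg_block(double v) {
  double z = (v + 80.0) / 60.0;
  z *= z;
  return z / (1.0 + z);
}

}  // namespace

// [[Rcpp::export]]
List engine_run(List pops_in, List groups_in, List recept, List drive,
                double dt, double duration_ms, double delay_ms,
                List probes_in, bool record_spikes = true,
                double probe_start_ms = 0.0, double probe_end_ms = -1.0) {
  const int n_pops = pops_in.size();
  std::vector<Pop> pops(n_pops);
  for (int p = 0; p < n_pops; ++p) {
    List pi = pops_in[p];
    Pop &P = pops[p];
    P.name = as<std::string>(pi["name"]);
    P.n = as<int>(pi["n"]);
    P.C = as<double>(pi["C"]);       P.k = as<double>(pi["k"]);
    P.vr = as<double>(pi["Vr"]);     P.vt = as<double>(pi["Vt"]);
    P.a = as<double>(pi["a"]);       P.b = as<double>(pi["b"]);
    P.vpeak = as<double>(pi["Vpeak"]);
    P.vreset = as<double>(pi["Vreset"]);
    P.d = as<double>(pi["d"]);
    P.v.assign(P.n, P.vr);
    P.u.assign(P.n, 0.0);
    P.I.assign(P.n, 0.0);
    if (pi.containsElementNamed("v0")) {
      NumericVector v0 = pi["v0"];
      if ((int)v0.size() != P.n) stop("engine: v0 length mismatch");
      for (int i = 0; i < P.n; ++i) P.v[i] = v0[i];
    }
  }

  const int n_groups = groups_in.size();
  std::vector<Group> groups(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    List gi = groups_in[g];
    Group &G = groups[g];
    G.pre_pop = as<int>(gi["pre_pop"]);
    G.post_pop = as<int>(gi["post_pop"]);
    IntegerVector pre = gi["pre"];   // 0-based, sorted ascending
    IntegerVector post = gi["post"]; // 0-based
    NumericVector w = gi["w"];
    const int n_pre = pops[G.pre_pop].n;
    const int n_edges = pre.size();
    G.row_ptr.assign(n_pre + 1, 0);
    for (int e = 0; e < n_edges; ++e) G.row_ptr[pre[e] + 1]++;
    for (int i = 0; i < n_pre; ++i) G.row_ptr[i + 1] += G.row_ptr[i];
    G.post.resize(n_edges);
    G.w.resize(n_edges);
    // `pre` arrives sorted, so edges are already in CSR order
    for (int e = 0; e < n_edges; ++e) {
      if (e > 0 && pre[e] < pre[e - 1]) stop("engine: edge list not sorted by pre");
      G.post[e] = post[e];
      G.w[e] = w[e];
    }
    G.eu.assign(n_edges, 0.0);
    G.ex.assign(n_edges, 1.0);
    G.last_t.assign(n_edges, 0.0);
    G.g_fast = as<double>(gi["g_fast"]);
    G.tau_d_fast = as<double>(gi["tau_d_fast"]);
    G.U = as<double>(gi["U"]);
    G.tau_u = as<double>(gi["tau_u"]);
    G.tau_x = as<double>(gi["tau_x"]);
    G.g_slow = as<double>(gi["g_slow"]);
    G.tau_d_slow = as<double>(gi["tau_d_slow"]);
    G.inhib = as<bool>(gi["inhib"]);
    G.df_fast = std::exp(-dt / G.tau_d_fast);
    G.df_slow = std::exp(-dt / G.tau_d_slow);
    G.s_fast.assign(pops[G.post_pop].n, 0.0);
    G.s_slow.assign(pops[G.post_pop].n, 0.0);
  }

  const double E_fe = as<double>(recept["E_fast_exc"]);
  const double E_se = as<double>(recept["E_slow_exc"]);
  const double E_fi = as<double>(recept["E_fast_inh"]);
  const double E_si = as<double>(recept["E_slow_inh"]);

  // External drive
  const int conj_pop = as<int>(drive["conj_pop"]);
  const double conj_I0 = as<double>(drive["conj_I0"]);
  const double conj_alpha = as<double>(drive["conj_alpha"]);
  IntegerVector conj_dir = drive["conj_dir"];     // 0..3 per conjunctive cell
  NumericVector theta4 = drive["theta4"];         // preferred angle per class
  NumericVector conj_eta = drive["conj_eta"];     // static baseline jitter (pA)
  const int place_pop = as<int>(drive["place_pop"]);
  const double place_A = as<double>(drive["place_A"]);
  const double place_sigma = as<double>(drive["place_sigma"]);
  IntegerVector place_col = drive["place_col"];
  IntegerVector place_row = drive["place_row"];
  NumericVector place_colx = drive["place_colx"]; // x (cm) per lattice column
  NumericVector place_rowy = drive["place_rowy"]; // y (cm) per lattice row
  const int stell_pop = as<int>(drive["stell_pop"]);
  const double settle_ms = as<double>(drive["settle_ms"]);
  NumericVector settle_amp = drive["settle_amp"]; // per stellate
  const double settle_tau = as<double>(drive["settle_tau"]);
  NumericVector pos_x = drive["x"], pos_y = drive["y"];
  NumericVector speed = drive["speed"], heading = drive["heading"];

  const int n_steps = (int)std::ceil(duration_ms / dt - 1e-9);
  const int delay_steps = std::max(1, (int)std::lround(delay_ms / dt));
  const int n_slots = delay_steps + 1;
  std::vector<std::vector<std::pair<int, int>>> delay_buf(n_slots);

  // Spike records
  std::vector<std::vector<int>> spk_idx(n_pops);
  std::vector<std::vector<double>> spk_t(n_pops);

  // Probes: record v and per-group fast/slow currents each ms
  const int n_probes = probes_in.size();
  if (probe_end_ms < 0) probe_end_ms = duration_ms;
  std::vector<int> probe_pop(n_probes), probe_idx(n_probes);
  for (int q = 0; q < n_probes; ++q) {
    IntegerVector pr = probes_in[q];
    probe_pop[q] = pr[0];
    probe_idx[q] = pr[1];
    if (probe_pop[q] < 0 || probe_pop[q] >= n_pops ||
        probe_idx[q] < 0 || probe_idx[q] >= pops[probe_pop[q]].n)
      stop("engine: probe addresses a non-existent neuron");
  }
  const int n_rec = std::max(0, (int)std::floor(probe_end_ms - probe_start_ms));
  std::vector<NumericVector> probe_v;
  std::vector<NumericMatrix> probe_I;
  for (int q = 0; q < n_probes; ++q) {
    probe_v.push_back(NumericVector(n_rec));
    probe_I.push_back(NumericMatrix(n_rec, 2 * n_groups));
  }

  // Per-ms external currents
  std::vector<double> conj_I(conj_pop >= 0 ? pops[conj_pop].n : 0, 0.0);
  std::vector<double> place_I(place_pop >= 0 ? pops[place_pop].n : 0, 0.0);
  std::vector<double> ex_col(place_colx.size()), ex_row(place_rowy.size());
  std::vector<double> stell_I(stell_pop >= 0 ? pops[stell_pop].n : 0, 0.0);
  int cur_ms = -1;

  const int n_ms_frames = pos_x.size();
  const double inv2s2 = 1.0 / (2.0 * place_sigma * place_sigma);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const int ms = (int)(t + 1e-9);

    if (ms != cur_ms) {
      cur_ms = ms;
      const int fr = ms < n_ms_frames ? ms : n_ms_frames - 1;
      if (conj_pop >= 0) {
        double tune[4];
        for (int c = 0; c < 4; ++c)
          tune[c] = conj_I0 + conj_alpha * speed[fr] *
                    (1.0 + std::cos(heading[fr] - theta4[c])) / 2.0;
        for (size_t i = 0; i < conj_I.size(); ++i) {
          double I = tune[conj_dir[i]] + conj_eta[i];
          conj_I[i] = I > 0.0 ? I : 0.0;
        }
      }
      if (place_pop >= 0) {
        for (int c = 0; c < (int)ex_col.size(); ++c) {
          double dx = pos_x[fr] - place_colx[c];
          ex_col[c] = std::exp(-dx * dx * inv2s2);
        }
        for (int r = 0; r < (int)ex_row.size(); ++r) {
          double dy = pos_y[fr] - place_rowy[r];
          ex_row[r] = std::exp(-dy * dy * inv2s2);
        }
        for (size_t i = 0; i < place_I.size(); ++i)
          place_I[i] = place_A * ex_col[place_col[i]] * ex_row[place_row[i]];
      }
      if (stell_pop >= 0) {
        const double env = (t < settle_ms) ? std::exp(-t / settle_tau) : 0.0;
        for (size_t i = 0; i < stell_I.size(); ++i)
          stell_I[i] = settle_amp[i] * env;
      }
      if (step % 2000 == 0) Rcpp::checkUserInterrupt();
    }

    // 1. conductance decay
    for (auto &G : groups) {
      for (auto &s : G.s_fast) s *= G.df_fast;
      for (auto &s : G.s_slow) s *= G.df_slow;
    }

    // 2. deliver delayed spikes (TM release)
    {
      auto &slot = delay_buf[step % n_slots];
      for (auto &pr : slot) {
        const int pop = pr.first, idx = pr.second;
        for (auto &G : groups) {
          if (G.pre_pop != pop) continue;
          for (int e = G.row_ptr[idx]; e < G.row_ptr[idx + 1]; ++e) {
            const double dt_ev = t - G.last_t[e];
            double u = G.eu[e] * std::exp(-dt_ev / G.tau_u);
            double x = 1.0 - (1.0 - G.ex[e]) * std::exp(-dt_ev / G.tau_x);
            u += G.U * (1.0 - u);
            const double R = u * x;
            x -= R;
            G.eu[e] = u;
            G.ex[e] = x;
            G.last_t[e] = t;
            const double wR = G.w[e] * R;
            G.s_fast[G.post[e]] += G.g_fast * wR;
            G.s_slow[G.post[e]] += G.g_slow * wR;
          }
        }
      }
      slot.clear();
    }

    // 3. input currents: external then synaptic
    for (auto &P : pops) std::fill(P.I.begin(), P.I.end(), 0.0);
    if (conj_pop >= 0) {
      auto &I = pops[conj_pop].I;
      for (size_t i = 0; i < conj_I.size(); ++i) I[i] += conj_I[i];
    }
    if (place_pop >= 0) {
      auto &I = pops[place_pop].I;
      for (size_t i = 0; i < place_I.size(); ++i) I[i] += place_I[i];
    }
    if (stell_pop >= 0 && t < settle_ms) {
      auto &I = pops[stell_pop].I;
      for (size_t i = 0; i < stell_I.size(); ++i) I[i] += stell_I[i];
    }
    for (auto &G : groups) {
      Pop &P = pops[G.post_pop];
      if (G.inhib) {
        for (int j = 0; j < P.n; ++j)
          P.I[j] += G.s_fast[j] * (E_fi - P.v[j]) +
                    G.s_slow[j] * (E_si - P.v[j]);
      } else {
        for (int j = 0; j < P.n; ++j)
          P.I[j] += G.s_fast[j] * (E_fe - P.v[j]) +
                    G.s_slow[j] * (E_se - P.v[j]) * mg_block(P.v[j]);
      }
    }

    // 4. neuron update with spike-and-reset
    const int slot_out = (step + delay_steps) % n_slots;
    for (int p = 0; p < n_pops; ++p) {
      Pop &P = pops[p];
      const double half = dt / 2.0;
      for (int i = 0; i < P.n; ++i) {
        double v = P.v[i], u = P.u[i];
        const double I = P.I[i];
        v += half * (P.k * (v - P.vr) * (v - P.vt) - u + I) / P.C;
        v += half * (P.k * (v - P.vr) * (v - P.vt) - u + I) / P.C;
        u += dt * P.a * (P.b * (v - P.vr) - u);
        if (v >= P.vpeak) {
          v = P.vreset;
          u += P.d;
          delay_buf[slot_out].push_back({p, i});
          if (record_spikes) {
            spk_idx[p].push_back(i + 1);
            spk_t[p].push_back(t + dt);
          }
        }
        P.v[i] = v;
        P.u[i] = u;
      }
    }

    // 5. probes at ms resolution (record at the last substep of each ms)
    if (n_probes > 0) {
      const double t_next = (step + 1) * dt;
      if (std::fabs(t_next - std::round(t_next)) < 1e-9) {
        const int rec = (int)std::round(t_next) - 1 - (int)probe_start_ms;
        if (rec >= 0 && rec < n_rec) {
          for (int q = 0; q < n_probes; ++q) {
            const Pop &P = pops[probe_pop[q]];
            probe_v[q][rec] = P.v[probe_idx[q]];
            for (int g = 0; g < n_groups; ++g) {
              const Group &G = groups[g];
              if (G.post_pop != probe_pop[q]) continue;
              const int j = probe_idx[q];
              const double v = P.v[j];
              if (G.inhib) {
                probe_I[q](rec, 2 * g) = G.s_fast[j] * (E_fi - v);
                probe_I[q](rec, 2 * g + 1) = G.s_slow[j] * (E_si - v);
              } else {
                probe_I[q](rec, 2 * g) = G.s_fast[j] * (E_fe - v);
                probe_I[q](rec, 2 * g + 1) =
                    G.s_slow[j] * (E_se - v) * mg_block(v);
              }
            }
          }
        }
      }
    }

    // 6. periodic state validation
    if (step % 1000 == 999) {
      for (int p = 0; p < n_pops; ++p) {
        for (int i = 0; i < pops[p].n; ++i) {
          if (!std::isfinite(pops[p].v[i]) || !std::isfinite(pops[p].u[i])) {
            stop("engine: non-finite state in population '%s' (neuron %d) at step %d",
                 pops[p].name.c_str(), i + 1, step);
          }
        }
      }
    }
  }

  List spikes(n_pops);
  for (int p = 0; p < n_pops; ++p) {
    spikes[p] = List::create(_["neuron"] = wrap(spk_idx[p]),
                             _["t_ms"] = wrap(spk_t[p]));
  }
  List probes_out(n_probes);
  NumericVector probe_t(n_rec);
  for (int r = 0; r < n_rec; ++r) probe_t[r] = probe_start_ms + r + 1;
  for (int q = 0; q < n_probes; ++q) {
    probes_out[q] = List::create(_["v"] = probe_v[q], _["I"] = probe_I[q],
                                 _["t_ms"] = probe_t);
  }
  List final_state(n_pops);
  for (int p = 0; p < n_pops; ++p) {
    final_state[p] = List::create(_["v"] = wrap(pops[p].v),
                                  _["u"] = wrap(pops[p].u));
  }
  return List::create(_["spikes"] = spikes, _["probes"] = probes_out,
                      _["final_state"] = final_state,
                      _["n_steps"] = n_steps);
}
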
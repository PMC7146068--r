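#include <Rcpp.h>
#include <chrono>
#include "cbsim.h"
using namespace Rcpp;

namespace {

struct Receptor { int chan; double impulse; };

struct Proj {
  int pre_pop;
  const double* offsets;   // length n_pre + 1
  const int* targets;      // post-local indices
  std::vector<Receptor> receptors;
};

struct Pop {
  int n, per_tile, gid_base;
  double k_m;              // dt / tau_m
  double theta, v_reset, e_rest, i_ex;
  int t_ref_steps;
  int mode;                // 0 = LIF, 1 = poisson emission
  double rate_dt;          // rate * dt (poisson)
  double sin_amp, sin_omega, sin_phase, const_cur;
  bool record;
  std::vector<int> chans;  // channel ids owned by this population
};

inline double now_s() {
  return std::chrono::duration<double>(
      std::chrono::steady_clock::now().time_since_epoch()).count();
}

}  // namespace

// Advance the whole network by forward Euler at fixed dt.
//
// Per step: (1) spikes emitted at the end of the previous step are delivered
// as impulses (+w*e) to the h stage of their target receptor filters —
// a one-step synaptic delay for every projection, including cross-tile ones;
// (2) per tile and population, filters advance by the exact exponential
// integrator and non-refractory membranes take one Euler step of
//   tau_m dv/dt = -(v - e_rest) - sum_r g_r (v - e_rev_r) + i_ex + drive(t);
// threshold crossings emit a spike at the step's end time, reset v and start
// the refractory clamp. Poisson-driven populations emit with probability
// rate*dt per step from a counter-based stream keyed by (seed, gid, step).
//
// `scheduler` 1 walks tile-by-tile (timing attributed per tile), 0 walks each
// population whole; both orders produce bit-identical spike output.
// [[Rcpp::export]]
List cpp_run_simulation(List pops_in, List chans_in, List projs_in,
                        int n_steps, double dt, double seed_lo, double seed_hi,
                        int n_tiles, int scheduler, IntegerVector halo_flag) {
  const uint64_t seed = ((uint64_t)(uint32_t)(int64_t)seed_hi << 32) |
                        (uint64_t)(uint32_t)(int64_t)seed_lo;
  const int n_pop = pops_in.size();

  std::vector<Pop> pops(n_pop);
  int N = 0;
  for (int p = 0; p < n_pop; ++p) {
    List pl = pops_in[p];
    Pop& P = pops[p];
    P.n = as<int>(pl["n"]);
    P.per_tile = as<int>(pl["per_tile"]);
    P.gid_base = as<int>(pl["gid_base"]);
    const double tau_m = as<double>(pl["tau_m"]);
    P.k_m = dt / tau_m;
    P.theta = as<double>(pl["theta"]);
    P.v_reset = as<double>(pl["v_reset"]);
    P.e_rest = as<double>(pl["e_rest"]);
    P.i_ex = as<double>(pl["i_ex"]);
    P.t_ref_steps = as<int>(pl["t_ref_steps"]);
    P.mode = as<int>(pl["mode"]);
    P.rate_dt = as<double>(pl["rate_hz"]) * dt * 1e-3;
    P.sin_amp = as<double>(pl["sin_amp"]);
    const double period = as<double>(pl["sin_period"]);
    P.sin_omega = (period > 0) ? 2.0 * M_PI / period : 0.0;
    P.sin_phase = as<double>(pl["sin_phase"]);
    P.const_cur = as<double>(pl["const_cur"]);
    P.record = as<bool>(pl["record"]);
    N += P.n;
  }

  // channel filter banks (flat storage; one bank per (population, channel))
  const int n_chan = chans_in.size();
  std::vector<AlphaChannel> chan(n_chan);
  std::vector<double> chan_erev(n_chan);
  std::vector<long long> chan_off(n_chan + 1, 0);
  for (int c = 0; c < n_chan; ++c) {
    List cl = chans_in[c];
    const int p = as<int>(cl["pop"]);
    chan[c].init(dt, as<double>(cl["tau_syn"]));
    chan_erev[c] = as<double>(cl["e_rev"]);
    pops[p].chans.push_back(c);
    chan_off[c + 1] = chan_off[c] + pops[p].n;
  }
  std::vector<double> g_all(chan_off[n_chan], 0.0), h_all(chan_off[n_chan], 0.0);

  std::vector<Proj> projs(projs_in.size());
  std::vector<std::vector<int>> proj_by_pop(n_pop);
  std::vector<NumericVector> keep_off(projs_in.size());
  std::vector<IntegerVector> keep_tgt(projs_in.size());
  for (int j = 0; j < (int)projs_in.size(); ++j) {
    List jl = projs_in[j];
    projs[j].pre_pop = as<int>(jl["pre_pop"]);
    keep_off[j] = as<NumericVector>(jl["offsets"]);
    keep_tgt[j] = as<IntegerVector>(jl["targets"]);
    projs[j].offsets = REAL(keep_off[j]);
    projs[j].targets = INTEGER(keep_tgt[j]);
    List rl = jl["receptors"];
    for (int r = 0; r < rl.size(); ++r) {
      List rr = rl[r];
      projs[j].receptors.push_back(
          {as<int>(rr["chan"]), as<double>(rr["impulse"])});
    }
    proj_by_pop[projs[j].pre_pop].push_back(j);
  }

  // state
  std::vector<double> v(N);
  std::vector<int> refr(N, 0);
  std::vector<uint8_t> pop_of(N);
  for (int p = 0; p < n_pop; ++p) {
    std::fill(v.begin() + pops[p].gid_base,
              v.begin() + pops[p].gid_base + pops[p].n, pops[p].e_rest);
    std::fill(pop_of.begin() + pops[p].gid_base,
              pop_of.begin() + pops[p].gid_base + pops[p].n, (uint8_t)p);
  }

  std::vector<int> rec_step, rec_gid;
  std::vector<int> prev, cur;
  std::vector<int> halo_buf;  // per-step outgoing border spikes
  std::vector<double> neuron_s(n_tiles, 0.0);
  std::vector<double> syn_edges(n_tiles, 0.0), comm_spk(n_tiles, 0.0);
  double syn_s = 0.0, comm_s = 0.0;
  const bool have_halo = halo_flag.size() == N;
  const double t_start = now_s();

  for (int step = 0; step < n_steps; ++step) {
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
    const double t_ms = step * dt;

    // (1) synaptic propagation of last step's spikes
    double t0 = now_s();
    for (int gid : prev) {
      const int p = pop_of[gid];
      const int local = gid - pops[p].gid_base;
      const int tile = local / pops[p].per_tile;
      for (int j : proj_by_pop[p]) {
        const Proj& pr = projs[j];
        const long long e0 = (long long)pr.offsets[local];
        const long long e1 = (long long)pr.offsets[local + 1];
        for (const Receptor& rc : pr.receptors) {
          double* hb = h_all.data() + chan_off[rc.chan];
          const double w = rc.impulse;
          for (long long e = e0; e < e1; ++e) hb[pr.targets[e]] += w;
        }
        syn_edges[tile] += (double)(e1 - e0) * pr.receptors.size();
      }
    }
    syn_s += now_s() - t0;

    // (2) halo exchange bookkeeping: copy border-region spikes into the
    // per-step buffer a neighboring tile would receive
    if (n_tiles > 1 && have_halo) {
      t0 = now_s();
      halo_buf.clear();
      for (int gid : prev) {
        if (halo_flag[gid]) {
          halo_buf.push_back(gid);
          const int p = pop_of[gid];
          comm_spk[(gid - pops[p].gid_base) / pops[p].per_tile] += 1.0;
        }
      }
      comm_s += now_s() - t0;
    }

    // (3) neuron update, per tile (or whole populations when scheduler = 0)
    cur.clear();
    const int n_seg_tiles = (scheduler == 1) ? n_tiles : 1;
    for (int tile = 0; tile < n_seg_tiles; ++tile) {
      t0 = now_s();
      for (int p = 0; p < n_pop; ++p) {
        Pop& P = pops[p];
        const int lo = (scheduler == 1) ? tile * P.per_tile : 0;
        const int hi = (scheduler == 1) ? lo + P.per_tile : P.n;
        const int base = P.gid_base;

        if (P.mode == 1) {  // poisson emission replaces intrinsic dynamics
          if (P.rate_dt > 0.0) {
            for (int i = lo; i < hi; ++i) {
              if (cb_hash_uniform(seed, (uint64_t)(base + i), (uint64_t)step)
                  < P.rate_dt) cur.push_back(base + i);
            }
          }
          continue;
        }

        double drive = P.i_ex + P.const_cur;
        if (P.sin_amp != 0.0) {
          drive += P.sin_amp *
                   (1.0 - std::cos(P.sin_omega * t_ms + P.sin_phase)) * 0.5;
        }
        const int nc = (int)P.chans.size();
        double* vv = v.data();
        int* rf = refr.data();

        if (nc == 0) {
          for (int i = lo; i < hi; ++i) {
            const int q = base + i;
            if (rf[q] > 0) { --rf[q]; vv[q] = P.v_reset; continue; }
            double vi = vv[q];
            vi += P.k_m * (-(vi - P.e_rest) + drive);
            if (vi >= P.theta) {
              cur.push_back(q); vv[q] = P.v_reset; rf[q] = P.t_ref_steps;
            } else vv[q] = vi;
          }
        } else if (nc == 1) {
          const int c0 = P.chans[0];
          double* g0 = g_all.data() + chan_off[c0];
          double* h0 = h_all.data() + chan_off[c0];
          const double d0 = chan[c0].d, w0 = chan[c0].dcc, e0 = chan_erev[c0];
          for (int i = lo; i < hi; ++i) {
            const int q = base + i;
            const double gg = d0 * g0[i] + w0 * h0[i];
            g0[i] = gg; h0[i] *= d0;
            if (rf[q] > 0) { --rf[q]; vv[q] = P.v_reset; continue; }
            double vi = vv[q];
            vi += P.k_m * (-(vi - P.e_rest) - gg * (vi - e0) + drive);
            if (vi >= P.theta) {
              cur.push_back(q); vv[q] = P.v_reset; rf[q] = P.t_ref_steps;
            } else vv[q] = vi;
          }
        } else {  // two receptor banks (the maximum in the shipped models)
          const int c0 = P.chans[0], c1 = P.chans[1];
          double* g0 = g_all.data() + chan_off[c0];
          double* h0 = h_all.data() + chan_off[c0];
          double* g1 = g_all.data() + chan_off[c1];
          double* h1 = h_all.data() + chan_off[c1];
          const double d0 = chan[c0].d, w0 = chan[c0].dcc, e0 = chan_erev[c0];
          const double d1 = chan[c1].d, w1 = chan[c1].dcc, e1 = chan_erev[c1];
          for (int i = lo; i < hi; ++i) {
            const int q = base + i;
            const double ga = d0 * g0[i] + w0 * h0[i];
            g0[i] = ga; h0[i] *= d0;
            const double gb = d1 * g1[i] + w1 * h1[i];
            g1[i] = gb; h1[i] *= d1;
            if (rf[q] > 0) { --rf[q]; vv[q] = P.v_reset; continue; }
            double vi = vv[q];
            vi += P.k_m * (-(vi - P.e_rest) - ga * (vi - e0) - gb * (vi - e1)
                           + drive);
            if (vi >= P.theta) {
              cur.push_back(q); vv[q] = P.v_reset; rf[q] = P.t_ref_steps;
            } else vv[q] = vi;
          }
        }
      }
      const double el = now_s() - t0;
      neuron_s[(scheduler == 1) ? tile : 0] += el;
    }

    if (scheduler == 1 && n_tiles > 1) std::sort(cur.begin(), cur.end());

    for (int gid : cur) {
      if (pops[pop_of[gid]].record) {
        rec_step.push_back(step + 1);  // spike time = end of the step
        rec_gid.push_back(gid);
      }
    }
    prev.swap(cur);

    if ((step & 255) == 0) {
      for (int p = 0; p < n_pop; ++p) {
        if (pops[p].mode == 1) continue;
        const double vi = v[pops[p].gid_base];
        if (!std::isfinite(vi)) {
          stop("numerical overflow: non-finite membrane potential in "
               "population %d at step %d", p, step);
        }
      }
    }
  }
  const double total_s = now_s() - t_start;

  // apportion the measured synapse/communication phase times across tiles in
  // proportion to the work (delivered edges, transferred spikes) each caused
  NumericMatrix timing(n_tiles, 4);
  double tot_e = 0.0, tot_c = 0.0;
  for (int t = 0; t < n_tiles; ++t) { tot_e += syn_edges[t]; tot_c += comm_spk[t]; }
  for (int t = 0; t < n_tiles; ++t) {
    timing(t, 0) = neuron_s[t];
    timing(t, 1) = (tot_e > 0) ? syn_s * syn_edges[t] / tot_e
                               : ((t == 0) ? syn_s : 0.0);
    timing(t, 2) = (tot_c > 0) ? comm_s * comm_spk[t] / tot_c : 0.0;
    timing(t, 3) = total_s / n_tiles;
  }

  return List::create(_["step"] = wrap(rec_step), _["gid"] = wrap(rec_gid),
                      _["timing"] = timing);
}
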
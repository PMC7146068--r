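#include <Rcpp.h>
#include "cbsim.h"
using namespace Rcpp;

// Realize one projection as a per-presynaptic-neuron adjacency (CSR).
//
// Pre neurons are visited in gid order; a fresh RNG sub-stream is opened per
// (seed, projection, pre tile), so tile wirings are mutually independent.
// Post neurons live on a regular lattice: per tile `n_sheets` sheets of
// nx x ny cells with spacing tile_size/nx; candidate windows are enumerated
// directly on that lattice in a fixed (sheet, row, column) order.
//
// kernel_type 0: 2-D Gaussian  p(d) = p * exp(-d^2 / (2 sigma^2)), d <= cutoff
// kernel_type 1: orthogonal cross: uniform p inside |dx| <= pre_width,
//                |dy| <= post_width / 2 (mediolateral extent 2*pre_width,
//                rostrocaudal extent post_width, centered on the pre cell)
//
// boundary 0: open (windows clamp at the domain edge)
// boundary 1: periodic (minimal-image wrap; windows clamp to one full period)
// [[Rcpp::export]]
List cpp_realize_projection(NumericVector pre_x, NumericVector pre_y,
                            IntegerVector pre_tile,
                            int kernel_type, double p, double sigma,
                            double cutoff, double pre_width, double post_width,
                            int ntx, int nty, int post_nx, int post_ny,
                            int post_nsheets, double tile_size,
                            int boundary, double seed_lo, double seed_hi,
                            int proj_id, bool same_pop) {
  const int n_pre = pre_x.size();
  const int ncols = ntx * post_nx;
  const int nrows = nty * post_ny;
  const double h = tile_size / post_nx;
  const double hy = tile_size / post_ny;
  const double Lx = ntx * tile_size, Ly = nty * tile_size;
  const int per_tile = post_nsheets * post_nx * post_ny;
  const uint64_t seed = ((uint64_t)(uint32_t)(int64_t)seed_hi << 32) |
                        (uint64_t)(uint32_t)(int64_t)seed_lo;

  const double rx = (kernel_type == 0) ? cutoff : pre_width;
  const double ry = (kernel_type == 0) ? cutoff : post_width / 2.0;
  const double cut2 = cutoff * cutoff;
  const double inv2s2 = (kernel_type == 0) ? 1.0 / (2.0 * sigma * sigma) : 0.0;

  std::vector<double> offsets(n_pre + 1, 0.0);
  std::vector<int> targets;
  targets.reserve(1024);

  int cur_tile = -1;
  CbRng rng(0, 0, 0);

  for (int k = 0; k < n_pre; ++k) {
    if (pre_tile[k] != cur_tile) {
      cur_tile = pre_tile[k];
      rng = CbRng(seed, (uint64_t)proj_id, (uint64_t)cur_tile);
    }
    const double px = pre_x[k], py = pre_y[k];

    int clo = (int)std::ceil((px - rx) / h - 0.5 - 1e-12);
    int chi = (int)std::floor((px + rx) / h - 0.5 + 1e-12);
    int rlo = (int)std::ceil((py - ry) / hy - 0.5 - 1e-12);
    int rhi = (int)std::floor((py + ry) / hy - 0.5 + 1e-12);
    if (boundary == 0) {
      clo = std::max(clo, 0); chi = std::min(chi, ncols - 1);
      rlo = std::max(rlo, 0); rhi = std::min(rhi, nrows - 1);
    } else {
      if (chi - clo + 1 >= ncols) { clo = 0; chi = ncols - 1; }
      if (rhi - rlo + 1 >= nrows) { rlo = 0; rhi = nrows - 1; }
    }

    for (int s = 0; s < post_nsheets; ++s) {
      for (int r = rlo; r <= rhi; ++r) {
        const int gy = (boundary == 1) ? ((r % nrows) + nrows) % nrows : r;
        double dy = (gy + 0.5) * hy - py;
        if (boundary == 1) dy -= Ly * std::nearbyint(dy / Ly);
        if (std::fabs(dy) > ry + 1e-12) continue;
        for (int c = clo; c <= chi; ++c) {
          const int gx = (boundary == 1) ? ((c % ncols) + ncols) % ncols : c;
          double dx = (gx + 0.5) * h - px;
          if (boundary == 1) dx -= Lx * std::nearbyint(dx / Lx);

          double pc;
          if (kernel_type == 0) {
            const double d2 = dx * dx + dy * dy;
            if (d2 > cut2 + 1e-9) continue;
            pc = p * std::exp(-d2 * inv2s2);
          } else {
            if (std::fabs(dx) > rx + 1e-12) continue;
            pc = p;
          }
          const double u = rng.uniform();
          if (u < pc) {
            const int tx = gx / post_nx, ty = gy / post_ny;
            const int ix = gx % post_nx, iy = gy % post_ny;
            const int tile = ty * ntx + tx;
            const int local = ((tile * post_nsheets + s) * post_ny + iy) * post_nx + ix;
            if (same_pop && local == k) continue;  // no self-edge
            targets.push_back(local);
          }
        }
      }
    }
    offsets[k + 1] = (double)targets.size();
  }

  return List::create(_["offsets"] = wrap(offsets),
                      _["targets"] = wrap(targets));
}

// g(t) after a single impulse of weight w at step `spike_step`, using the
// engine's exact-exponential two-stage recurrence (same update as the engine).
// [[Rcpp::export]]
NumericVector cpp_alpha_filter_trace(int n_steps, int spike_step, double dt,
                                     double tau, double w) {
  AlphaChannel ch; ch.init(dt, tau);
  double g = 0.0, hh = 0.0;
  NumericVector out(n_steps + 1);
  for (int n = 0; n < n_steps; ++n) {
    if (n == spike_step) hh += w * M_E;
    const double h_old = hh;
    g = ch.d * g + ch.dcc * h_old;
    hh = ch.d * hh;
    out[n + 1] = g;
  }
  return out;
}
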
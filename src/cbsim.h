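#ifndef CBSIM_H
#define CBSIM_H

#include <cstdint>
#include <cmath>

// counter-based deterministic RNG (splitmix64). Streams are keyed by
// (seed, projection, tile) for wiring and by (seed, gid, step) for drivers,
// so realizations never depend on scheduling, partitioning or worker count.
static inline uint64_t cb_mix(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct CbRng {
  uint64_t state;
  CbRng(uint64_t seed, uint64_t a, uint64_t b) {
    state = cb_mix(seed ^ (0xA076'1D64'78BD'642FULL * (a + 1)));
    state = cb_mix(state ^ (0xE703'7ED1'A0B4'28DBULL * (b + 1)));
  }
  double uniform() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z ^= (z >> 31);
    return (z >> 11) * 0x1.0p-53;
  }
};

// stateless per-(seed, gid, step) uniform for Poisson drivers
static inline double cb_hash_uniform(uint64_t seed, uint64_t gid, uint64_t step) {
  uint64_t z = cb_mix(seed ^ (gid * 0xD6E8'FEB8'6659'FD93ULL)
                           ^ (step * 0xCA5A'8263'9512'1157ULL));
  return (z >> 11) * 0x1.0p-53;
}

// alpha-function synaptic filter, realized as two coupled first-order stages
//   tau h' = -h ; tau g' = h - g
// advanced with the exact exponential integrator over one step:
//   g <- d*g + d*(dt/tau)*h ; h <- d*h,   d = exp(-dt/tau).
// A spike impulse adds w*e to h, which makes g follow w*(t/tau)*exp(1 - t/tau)
// exactly at grid times (peak w at t = tau).
struct AlphaChannel {
  double d;    // exp(-dt/tau)
  double dcc;  // d * dt / tau
  void init(double dt, double tau) {
    d = std::exp(-dt / tau);
    dcc = d * dt / tau;
  }
};

#endif
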
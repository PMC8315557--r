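#ifndef MESOSIM_RNG_H
#define MESOSIM_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256++ with splitmix64 seeding: one independent, reproducible stream
// per realization, independent of R's global RNG state.
struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro(uint64_t seed, uint64_t stream = 0) {
    uint64_t x = seed ^ (0xA3C59AC2ULL + stream * 0x9E3779B97F4A7C15ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1]: never 0, safe for log()
  inline double unif_pos() {
    return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }

  // uniform on [0, 1)
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }

  inline double expo(double rate) { return -std::log(unif_pos()) / rate; }

  // standard normal, Box-Muller with caching
  bool have_spare = false;
  double spare = 0.0;
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u = unif_pos(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586476925286766559 * v;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }

  inline int randint(int n) {  // uniform on 0..n-1
    return (int)(unif() * n);
  }
};

#endif
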
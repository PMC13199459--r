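// Owen-scrambled base-2 radical-inverse (van der Corput) point sets.
//
// Nested uniform (Owen) scrambling is applied per observation with the
// hash-based permutation of Laine & Karras (as popularized by Burley's
// "Practical Hash-based Owen Scrambling"): the fixed-point bits of the
// radical inverse are bit-reversed, passed through a seeded avalanche-style
// permutation whose carries only propagate upward, and reversed back.
// This preserves the (0, m, 1)-net structure of the point set, giving the
// RMS integration error O(R^{-3/2}) of scrambled nets rather than the
// O(R^{-1}) of a plain random shift.

#include <Rcpp.h>
using namespace Rcpp;

static inline uint32_t reverse_bits32(uint32_t x) {
  x = (x << 16) | (x >> 16);
  x = ((x & 0x00ff00ffu) << 8) | ((x & 0xff00ff00u) >> 8);
  x = ((x & 0x0f0f0f0fu) << 4) | ((x & 0xf0f0f0f0u) >> 4);
  x = ((x & 0x33333333u) << 2) | ((x & 0xccccccccu) >> 2);
  x = ((x & 0x55555555u) << 1) | ((x & 0xaaaaaaaau) >> 1);
  return x;
}

static inline uint32_t laine_karras_permutation(uint32_t x, uint32_t seed) {
  x += seed;
  x ^= x * 0x6c50b47cu;
  x ^= x * 0xb82f1e52u;
  x ^= x * 0xc7afe638u;
  x ^= x * 0x8d22f6e6u;
  return x;
}

static inline uint32_t nested_uniform_scramble(uint32_t x, uint32_t seed) {
  x = reverse_bits32(x);
  x = laine_karras_permutation(x, seed);
  x = reverse_bits32(x);
  return x;
}

// n-by-R matrix of scrambled uniforms; row i uses scramble key seeds[i].
// The base points are the radical inverses of burn + 1, ..., burn + R.
// [[Rcpp::export]]
NumericMatrix owen_halton_cpp(int n, int R, int burn,
                              const IntegerVector& seeds) {
  NumericMatrix u(n, R);
  const double inv = 1.0 / 4294967296.0;  // 2^-32
  std::vector<uint32_t> base(R);
  for (int r = 0; r < R; ++r) {
    base[r] = reverse_bits32(static_cast<uint32_t>(burn + r + 1));
  }
  for (int i = 0; i < n; ++i) {
    const uint32_t key = static_cast<uint32_t>(seeds[i]);
    for (int r = 0; r < R; ++r) {
      const uint32_t s = nested_uniform_scramble(base[r], key);
      // center within the 2^-32 cell to stay strictly inside (0, 1)
      u(i, r) = (static_cast<double>(s) + 0.5) * inv;
    }
  }
  return u;
}
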
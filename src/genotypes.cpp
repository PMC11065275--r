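#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Dosage generation at cohort scale (tens of millions of draws per
// replicate) uses an internal xoshiro256++ stream, seeded from R's RNG so
// that set.seed() fully determines the output while avoiding the per-draw
// overhead of the R RNG API.

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // uniform on (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool has_spare = false;
  double spare = 0.0;
  inline double norm() {  // Box-Muller with caching
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

inline uint64_t seed_from_R() {
  // two 31-bit draws from the R stream give a 62-bit seed
  uint64_t a = (uint64_t)(unif_rand() * 2147483647.0);
  uint64_t b = (uint64_t)(unif_rand() * 2147483647.0);
  return (a << 31) ^ b;
}

inline void center_col(double* g, int n, double* sxx_out) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += g[i];
  double mu = s / n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) {
    g[i] -= mu;
    ss += g[i] * g[i];
  }
  *sxx_out = ss;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_dosage_independent(int n, NumericVector maf, bool center) {
  int m = maf.size();
  NumericMatrix G(n, m);
  NumericVector sxx(m);
  Xoshiro256pp rng(seed_from_R());
  for (int j = 0; j < m; ++j) {
    double p = maf[j];
    double p0 = (1.0 - p) * (1.0 - p);
    double p01 = p0 + 2.0 * p * (1.0 - p);
    double* g = &G(0, j);
    for (int i = 0; i < n; ++i) {
      double u = rng.unif();
      g[i] = (u > p0) + (u > p01);
    }
    if (center) center_col(g, n, &sxx[j]);
    else { double s = 0; for (int i = 0; i < n; ++i) s += g[i]*g[i]; sxx[j] = s; }
  }
  G.attr("sxx") = sxx;
  return G;
}

// Block-exchangeable dosages: within a block a latent Gaussian shares a
// common factor with loading sqrt(rho); the latent variable is dichotomised
// at the Hardy-Weinberg quantiles of each SNP's MAF so marginals remain
// Binomial(2, maf). block_id must be sorted, 1-based.
// [[Rcpp::export]]
NumericMatrix cpp_dosage_blocks(int n, NumericVector maf, IntegerVector block_id,
                                double rho, bool center) {
  int m = maf.size();
  if (block_id.size() != m) stop("block_id length must match maf");
  NumericMatrix G(n, m);
  NumericVector sxx(m);
  Xoshiro256pp rng(seed_from_R());
  double a = std::sqrt(rho), b = std::sqrt(1.0 - rho);
  std::vector<double> shared(n);
  int j = 0;
  while (j < m) {
    int cur = block_id[j];
    for (int i = 0; i < n; ++i) shared[i] = rng.norm();
    while (j < m && block_id[j] == cur) {
      double p = maf[j];
      double p0 = (1.0 - p) * (1.0 - p);
      double p01 = p0 + 2.0 * p * (1.0 - p);
      double t1 = R::qnorm(p0, 0.0, 1.0, 1, 0);
      double t2 = R::qnorm(p01, 0.0, 1.0, 1, 0);
      double* g = &G(0, j);
      for (int i = 0; i < n; ++i) {
        double z = a * shared[i] + b * rng.norm();
        g[i] = (z > t1) + (z > t2);
      }
      if (center) center_col(g, n, &sxx[j]);
      else { double s = 0; for (int i = 0; i < n; ++i) s += g[i]*g[i]; sxx[j] = s; }
      ++j;
    }
  }
  G.attr("sxx") = sxx;
  return G;
}
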
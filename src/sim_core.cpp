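// Genotype-level simulation core for the multi-study GWAS world.
//
// Genotypes are independent allele counts 0/1/2 at independent SNPs.
// A self-contained xoshiro256++ generator (seeded via splitmix64) makes
// every study/replicate a reproducible, platform-independent substream
// keyed by an integer seed; columns are regenerated on demand from
// per-column streams, so memory stays O(n) regardless of S.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// one genotype column from the column's own stream
inline void gen_column(int n, double f, uint64_t col_seed,
                       std::vector<double> &g) {
  Xoshiro rng(col_seed);
  const double p0 = (1.0 - f) * (1.0 - f);
  const double p01 = p0 + 2.0 * f * (1.0 - f);
  for (int i = 0; i < n; ++i) {
    const double u = rng.unif();
    g[i] = (u > p0) + (u > p01);
  }
}

// standardize in place; returns false when the column is monomorphic
inline bool standardize(std::vector<double> &g, double f,
                        bool sample_moments) {
  const int n = (int) g.size();
  double mu, sd;
  if (sample_moments) {
    double s = 0.0, ss = 0.0;
    for (double v : g) { s += v; ss += v * v; }
    mu = s / n;
    const double var = ss / n - mu * mu;
    if (var <= 0.0) return false;
    sd = std::sqrt(var);
  } else {
    mu = 2.0 * f;
    const double var = 2.0 * f * (1.0 - f);
    if (var <= 0.0) return false;
    sd = std::sqrt(var);
  }
  const double inv = 1.0 / sd;
  for (double &v : g) v = (v - mu) * inv;
  return true;
}

inline uint64_t column_seed(uint64_t base, int k) {
  uint64_t x = base ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(k + 1));
  return splitmix64(x);
}

} // namespace

// Simulate one study: phenotype from standardized genotypes plus Gaussian
// noise, per-SNP marginal regression (coefficient = sample correlation),
// and optionally the polygenic score of this sample under given weights.
// [[Rcpp::export]]
List sim_study_core(int n, NumericVector freq, NumericVector beta_std,
                    double env_sd, double seed, bool sample_moments,
                    Nullable<NumericVector> pgs_weights = R_NilValue) {
  const int S = freq.size();
  if (beta_std.size() != S) stop("beta_std must have one entry per SNP");
  if (n < 2) stop("need at least two individuals");
  const uint64_t base = (uint64_t) seed;
  std::vector<double> g((size_t) n), gen((size_t) n, 0.0);
  std::vector<char> mono((size_t) S, 0);

  // pass 1: genetic values from causal columns
  for (int k = 0; k < S; ++k) {
    if (beta_std[k] == 0.0) continue;
    gen_column(n, freq[k], column_seed(base, k), g);
    if (!standardize(g, freq[k], sample_moments)) { mono[k] = 1; continue; }
    const double b = beta_std[k];
    for (int i = 0; i < n; ++i) gen[i] += b * g[i];
  }

  // phenotype: genetic value + environmental noise, then standardized
  NumericVector y(n);
  {
    Xoshiro rng(base ^ 0xD1B54A32D192ED03ULL);
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      // Box-Muller
      const double u1 = 1.0 - rng.unif(), u2 = rng.unif();
      const double z = std::sqrt(-2.0 * std::log(u1)) *
                       std::cos(6.283185307179586 * u2);
      y[i] = gen[i] + env_sd * z;
      s += y[i];
    }
    const double mu = s / n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) { y[i] -= mu; ss += y[i] * y[i]; }
    const double sd = std::sqrt(ss / n);
    if (sd <= 0.0) stop("degenerate phenotype: zero variance");
    for (int i = 0; i < n; ++i) y[i] /= sd;
  }

  double gen_mean = 0.0, gen_ss = 0.0;
  for (int i = 0; i < n; ++i) gen_mean += gen[i];
  gen_mean /= n;
  for (int i = 0; i < n; ++i)
    gen_ss += (gen[i] - gen_mean) * (gen[i] - gen_mean);

  // pass 2: per-SNP correlations and optional PGS accumulation
  NumericVector r(S);
  LogicalVector excluded(S);
  NumericVector w;
  bool want_pgs = pgs_weights.isNotNull();
  NumericVector pgs;
  if (want_pgs) {
    w = pgs_weights.get();
    if (w.size() != S) stop("pgs_weights must have one entry per SNP");
    pgs = NumericVector(n);
  }
  for (int k = 0; k < S; ++k) {
    gen_column(n, freq[k], column_seed(base, k), g);
    if (mono[k] || !standardize(g, freq[k], sample_moments)) {
      excluded[k] = true;
      r[k] = NA_REAL;
      continue;
    }
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += g[i] * y[i];
    r[k] = dot / n;
    if (want_pgs && w[k] != 0.0 && !NumericVector::is_na(w[k])) {
      const double wk = w[k];
      for (int i = 0; i < n; ++i) pgs[i] += wk * g[i];
    }
  }

  List out = List::create(
    Named("coeff") = r,
    Named("excluded") = excluded,
    Named("y") = y,
    Named("gen_var") = gen_ss / n);
  if (want_pgs) out["pgs"] = pgs;
  return out;
}

// Raw genotype matrix from the same per-column streams (small designs:
// used by tests and oracle checks).
// [[Rcpp::export]]
IntegerMatrix sim_genotypes_core(int n, NumericVector freq, double seed) {
  const int S = freq.size();
  const uint64_t base = (uint64_t) seed;
  IntegerMatrix out(n, S);
  std::vector<double> g((size_t) n);
  for (int k = 0; k < S; ++k) {
    gen_column(n, freq[k], column_seed(base, k), g);
    for (int i = 0; i < n; ++i) out(i, k) = (int) g[i];
  }
  return out;
}
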
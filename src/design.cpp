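#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Signatures are handled as bitmasks over the L*P pools so that pair and
// triple statistics over millions of combinations stay cheap.

typedef std::vector<uint64_t> Mask;

static inline int popcnt64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int n = 0;
  while (x) { x &= x - 1; ++n; }
  return n;
#endif
}

static std::vector<Mask> signature_masks(const IntegerMatrix& sigs, int n_pools) {
  const int W = (n_pools + 63) / 64;
  const int n = sigs.nrow(), L = sigs.ncol();
  std::vector<Mask> m(n, Mask(W, 0ULL));
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < L; ++j) {
      int p = sigs(i, j);
      if (p < 0 || p >= n_pools) stop("pool index out of range");
      m[i][p >> 6] |= (1ULL << (p & 63));
    }
  }
  return m;
}

// [[Rcpp::export(name = ".pair_intersection_counts")]]
NumericVector pair_intersection_counts(IntegerMatrix sigs, int n_pools) {
  const int n = sigs.nrow(), L = sigs.ncol();
  const int W = (n_pools + 63) / 64;
  std::vector<Mask> m = signature_masks(sigs, n_pools);
  NumericVector out(L + 1);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int t = 0;
      for (int w = 0; w < W; ++w) t += popcnt64(m[a][w] & m[b][w]);
      out[t] += 1.0;
    }
  }
  return out;
}

// Shared-pool count of a triple {a,b,c}: 3L - |sig(a) u sig(b) u sig(c)|.
// Sampling uses R's RNG stream (distinct unordered triples, no repeats).
// [[Rcpp::export(name = ".triple_deficit_counts")]]
NumericVector triple_deficit_counts(IntegerMatrix sigs, int n_pools,
                                    double n_samples, bool enumerate_all) {
  const int n = sigs.nrow(), L = sigs.ncol();
  const int W = (n_pools + 63) / 64;
  std::vector<Mask> m = signature_masks(sigs, n_pools);
  NumericVector out(3 * L + 1);
  if (n < 3) stop("triple statistics require at least 3 items");
  if (enumerate_all) {
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b)
        for (int c = b + 1; c < n; ++c) {
          int u = 0;
          for (int w = 0; w < W; ++w)
            u += popcnt64(m[a][w] | m[b][w] | m[c][w]);
          out[3 * L - u] += 1.0;
        }
    return out;
  }
  if (n >= (1 << 21)) stop("sampled triple statistics support at most 2^21 items");
  std::unordered_set<uint64_t> seen;
  seen.reserve((size_t)(n_samples * 1.4));
  long long target = (long long)n_samples;
  long long done = 0;
  while (done < target) {
    int a = (int)R_unif_index(n);
    int b = (int)R_unif_index(n);
    int c = (int)R_unif_index(n);
    if (a == b || a == c || b == c) continue;
    int lo = std::min(a, std::min(b, c));
    int hi = std::max(a, std::max(b, c));
    int mid = a + b + c - lo - hi;
    uint64_t key = ((uint64_t)lo << 42) | ((uint64_t)mid << 21) | (uint64_t)hi;
    if (!seen.insert(key).second) continue;
    int u = 0;
    for (int w = 0; w < W; ++w)
      u += popcnt64(m[lo][w] | m[mid][w] | m[hi][w]);
    out[3 * L - u] += 1.0;
    ++done;
  }
  return out;
}
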
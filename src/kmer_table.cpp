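#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <set>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Canonical k-mer machinery. Bases are 2-bit coded (A=0, C=1, G=2, T=3) so
// numeric order on codes equals lexicographic order on strings; the canonical
// form of a k-mer is the smaller of its own code and its reverse complement's.
// ---------------------------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char bases[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

static uint64_t encode_kmer(const char* s, int k) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int v = base_code(s[i]);
    if (v < 0) stop("k-mer contains a non-ACGT symbol: %s", std::string(s, k).c_str());
    code = (code << 2) | (uint64_t)v;
  }
  return code;
}

static uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

// [[Rcpp::export(name = ".canonical_kmers")]]
CharacterVector canonical_kmers(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const char* s = CHAR(STRING_ELT(x, i));
    int k = LENGTH(STRING_ELT(x, i));
    if (k < 1 || k > 31) stop("k-mers must have length 1..31");
    uint64_t code = encode_kmer(s, k);
    uint64_t rc = revcomp_code(code, k);
    out[i] = decode_kmer(std::min(code, rc), k);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-pool k-mer count table: canonical k-mer -> vector of L*P counts.
// Counts saturate at `cap` (positivity and relative magnitude are all the
// downstream classification uses).
// ---------------------------------------------------------------------------

struct KCT {
  int k;
  int n_pools;
  uint32_t cap;
  std::unordered_map<uint64_t, size_t> index;  // code -> row
  std::vector<uint16_t> counts;                // rows x n_pools
};

// [[Rcpp::export(name = ".kct_new")]]
SEXP kct_new(int k, int n_pools, int cap) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  if (n_pools < 1) stop("n_pools must be positive");
  if (cap < 1 || cap > 65535) stop("count cap must be in 1..65535");
  KCT* t = new KCT();
  t->k = k;
  t->n_pools = n_pools;
  t->cap = (uint32_t)cap;
  return XPtr<KCT>(t, true);
}

// Counts every ACGT window of every read into pool `pool` (0-based).
// Returns the number of windows counted (for conservation checks).
// [[Rcpp::export(name = ".kct_add_reads")]]
double kct_add_reads(SEXP xp, CharacterVector seqs, int pool) {
  XPtr<KCT> t(xp);
  if (pool < 0 || pool >= t->n_pools) stop("pool index out of range");
  const int k = t->k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int np = t->n_pools;
  double n_windows = 0;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    const int len = LENGTH(STRING_ELT(seqs, r));
    uint64_t code = 0, rc = 0;
    int valid = 0;
    for (int i = 0; i < len; ++i) {
      int v = base_code(s[i]);
      if (v < 0) { valid = 0; code = 0; rc = 0; continue; }
      code = ((code << 2) | (uint64_t)v) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - v) << (2 * (k - 1)));
      if (++valid >= k) {
        uint64_t canon = std::min(code, rc);
        auto it = t->index.find(canon);
        size_t row;
        if (it == t->index.end()) {
          row = t->counts.size() / np;
          t->index.emplace(canon, row);
          t->counts.resize(t->counts.size() + np, 0);
        } else {
          row = it->second;
        }
        uint16_t& c = t->counts[row * np + pool];
        if ((uint32_t)c < t->cap) ++c;
        n_windows += 1;
      }
    }
  }
  return n_windows;
}

// [[Rcpp::export(name = ".kct_info")]]
List kct_info(SEXP xp) {
  XPtr<KCT> t(xp);
  return List::create(_["k"] = t->k, _["n_pools"] = t->n_pools,
                      _["n_kmers"] = (double)t->index.size(),
                      _["cap"] = (int)t->cap);
}

// [[Rcpp::export(name = ".kct_lookup")]]
IntegerMatrix kct_lookup(SEXP xp, CharacterVector kmers) {
  XPtr<KCT> t(xp);
  const int np = t->n_pools;
  IntegerMatrix out(kmers.size(), np);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    if (LENGTH(STRING_ELT(kmers, i)) != t->k) stop("k-mer length must equal table k");
    uint64_t code = encode_kmer(CHAR(STRING_ELT(kmers, i)), t->k);
    uint64_t canon = std::min(code, revcomp_code(code, t->k));
    auto it = t->index.find(canon);
    if (it != t->index.end()) {
      const uint16_t* row = &t->counts[it->second * np];
      for (int p = 0; p < np; ++p) out(i, p) = row[p];
    }
  }
  return out;
}

// Full table as (kmer, count matrix), sorted lexicographically; intended for
// small tables (exports, fixtures).
// [[Rcpp::export(name = ".kct_dump")]]
List kct_dump(SEXP xp) {
  XPtr<KCT> t(xp);
  const int np = t->n_pools;
  std::vector<std::pair<uint64_t, size_t> > items(t->index.begin(), t->index.end());
  std::sort(items.begin(), items.end());
  CharacterVector kmers(items.size());
  IntegerMatrix cnt(items.size(), np);
  for (size_t i = 0; i < items.size(); ++i) {
    kmers[i] = decode_kmer(items[i].first, t->k);
    const uint16_t* row = &t->counts[items[i].second * np];
    for (int p = 0; p < np; ++p) cnt(i, p) = row[p];
  }
  return List::create(_["kmer"] = kmers, _["counts"] = cnt);
}

// Histogram of support sizes w (number of pools with positive count) over all
// distinct stored k-mers; index i holds the tally for w = i (w = 0 unused).
// [[Rcpp::export(name = ".kct_support_hist")]]
NumericVector kct_support_hist(SEXP xp) {
  XPtr<KCT> t(xp);
  const int np = t->n_pools;
  NumericVector out(np + 1);
  const size_t rows = t->index.size();
  for (size_t r = 0; r < rows; ++r) {
    int w = 0;
    const uint16_t* row = &t->counts[r * np];
    for (int p = 0; p < np; ++p) w += (row[p] > 0);
    out[w] += 1.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Count-vector classification (the k-mer level of the deconvolution
// algorithm). A support of w positive pools is matched against single clone
// signatures, unions of two, or unions of three, in the band structure
//   w < L                      -> error_discard
//   w = L                      -> single-signature match
//   L < w < 2L-2G              -> drop w-L smallest counts, re-test single
//   2L-2G <= w <= 2L           -> two-signature union match
//   2L < w < 3L-3G             -> drop down to 2L, re-test pairs
//   3L-3G <= w <= 3L           -> three-signature union match
//   w > 3L                     -> repeat_discard
// Bands are evaluated strictly in this order; a failed match is `unmatched`.
// The entry of the read's own pool is never dropped (that pool genuinely
// contains the k-mer); ties among equal counts drop the lower pool index
// first.
// ---------------------------------------------------------------------------

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

struct ClsOut {
  int status;  // 0 error_discard, 1 assigned, 2 unmatched, 3 repeat_discard
  std::vector<int> clones;
  std::vector<int> support;  // matched (possibly reduced) support when assigned
};

class Classifier {
 public:
  int n, L, gamma, n_pools, W;
  std::vector<Mask> masks;
  IntegerMatrix sigs;

  Classifier(const IntegerMatrix& sigs_, int n_pools_, int gamma_)
      : n(sigs_.nrow()), L(sigs_.ncol()), gamma(gamma_), n_pools(n_pools_),
        W((n_pools_ + 63) / 64), sigs(sigs_) {
    masks.assign(n, Mask(W, 0ULL));
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < L; ++j) {
        int p = sigs(i, j);
        if (p < 0 || p >= n_pools) stop("signature pool index out of range");
        masks[i][p >> 6] |= (1ULL << (p & 63));
      }
  }

  Mask set_mask(const std::vector<int>& pools) const {
    Mask m(W, 0ULL);
    for (size_t i = 0; i < pools.size(); ++i)
      m[pools[i] >> 6] |= (1ULL << (pools[i] & 63));
    return m;
  }

  bool subset(const Mask& a, const Mask& b) const {  // a subset of b
    for (int w = 0; w < W; ++w)
      if (a[w] & ~b[w]) return false;
    return true;
  }

  std::vector<int> candidates(const Mask& s) const {
    std::vector<int> out;
    for (int i = 0; i < n; ++i)
      if (subset(masks[i], s)) out.push_back(i);
    return out;
  }

  // Drop the d smallest positive counts (never source_pool; ties by lower
  // pool index), returning the surviving pools sorted ascending.
  std::vector<int> drop_smallest(const std::vector<int>& pools,
                                 const std::vector<int>& cnts,
                                 int d, int source_pool) const {
    std::vector<std::pair<int, int> > order;  // (count, pool), droppable only
    order.reserve(pools.size());
    for (size_t i = 0; i < pools.size(); ++i)
      if (pools[i] != source_pool)
        order.push_back(std::make_pair(cnts[i], pools[i]));
    std::sort(order.begin(), order.end());
    std::set<int> dropped;
    for (int i = 0; i < d && i < (int)order.size(); ++i)
      dropped.insert(order[i].second);
    std::vector<int> kept;
    kept.reserve(pools.size() - dropped.size());
    for (size_t i = 0; i < pools.size(); ++i)
      if (!dropped.count(pools[i])) kept.push_back(pools[i]);
    return kept;
  }

  ClsOut match_single(const std::vector<int>& pools) const {
    ClsOut out; out.status = 2;
    if ((int)pools.size() != L) return out;
    Mask s = set_mask(pools);
    for (int i = 0; i < n; ++i) {
      if (subset(masks[i], s)) {  // |sig| == |s| == L, so subset => equality
        out.status = 1;
        out.clones.assign(1, i);
        out.support = pools;
        return out;
      }
    }
    return out;
  }

  ClsOut match_union(const std::vector<int>& pools, int arity) const {
    ClsOut out; out.status = 2;
    Mask s = set_mask(pools);
    std::vector<int> cand = candidates(s);
    const int w = (int)pools.size();
    const int nc = (int)cand.size();
    if (arity == 2) {
      for (int i = 0; i < nc; ++i)
        for (int j = i + 1; j < nc; ++j) {
          int u = 0;
          for (int ww = 0; ww < W; ++ww)
            u += popcnt64(masks[cand[i]][ww] | masks[cand[j]][ww]);
          if (u == w) {
            out.status = 1;
            out.clones.push_back(cand[i]);
            out.clones.push_back(cand[j]);
            out.support = pools;
            return out;
          }
        }
    } else {
      for (int i = 0; i < nc; ++i)
        for (int j = i + 1; j < nc; ++j)
          for (int l = j + 1; l < nc; ++l) {
            int u = 0;
            for (int ww = 0; ww < W; ++ww)
              u += popcnt64(masks[cand[i]][ww] | masks[cand[j]][ww] |
                            masks[cand[l]][ww]);
            if (u == w) {
              out.status = 1;
              out.clones.push_back(cand[i]);
              out.clones.push_back(cand[j]);
              out.clones.push_back(cand[l]);
              out.support = pools;
              return out;
            }
          }
    }
    return out;
  }

  ClsOut classify(const std::vector<int>& pools, const std::vector<int>& cnts,
                  int source_pool) const {
    ClsOut out; out.status = 0;
    const int w = (int)pools.size();
    const int u2lo = 2 * L - 2 * gamma, u2hi = 2 * L;
    const int u3lo = 3 * L - 3 * gamma, u3hi = 3 * L;
    if (w < L) { out.status = 0; return out; }
    if (w == L) return match_single(pools);
    if (w < u2lo) return match_single(drop_smallest(pools, cnts, w - L, source_pool));
    if (w <= u2hi) return match_union(pools, 2);
    if (w < u3lo) {
      std::vector<int> kept = drop_smallest(pools, cnts, w - u2hi, source_pool);
      return match_union(kept, 2);
    }
    if (w <= u3hi) return match_union(pools, 3);
    out.status = 3;
    return out;
  }
};

// [[Rcpp::export(name = ".classify_support")]]
List classify_support_cpp(IntegerVector counts, IntegerMatrix sigs, int n_pools,
                          int gamma, int source_pool) {
  if (counts.size() != n_pools) stop("count vector length must equal n_pools");
  if (source_pool < 0 || source_pool >= n_pools) stop("source_pool out of range");
  if (counts[source_pool] <= 0)
    stop("contract violation: source pool has zero count");
  Classifier cls(sigs, n_pools, gamma);
  std::vector<int> pools, cnts;
  for (int p = 0; p < n_pools; ++p) {
    if (counts[p] < 0) stop("counts must be nonnegative");
    if (counts[p] > 0) { pools.push_back(p); cnts.push_back(counts[p]); }
  }
  ClsOut r = cls.classify(pools, cnts, source_pool);
  return List::create(_["status"] = r.status,
                      _["clones"] = IntegerVector(r.clones.begin(), r.clones.end()),
                      _["matched_support"] = IntegerVector(r.support.begin(), r.support.end()));
}

// ---------------------------------------------------------------------------
// Read deconvolution for one pool of reads against the count table.
// Per read: classify each k-mer (memoised per distinct k-mer; within one call
// the source pool and the table are fixed), take the union B of the assigned
// k-mers' clone sets, and deconvolute iff 1 <= |B| <= 3.
// ---------------------------------------------------------------------------

struct MemoVal {
  int8_t status;
  int8_t nc;
  int32_t clones[3];
};

// [[Rcpp::export(name = ".kct_deconvolve")]]
List kct_deconvolve(SEXP xp, CharacterVector seqs, int source_pool,
                    IntegerMatrix sigs, int gamma) {
  XPtr<KCT> t(xp);
  const int k = t->k, np = t->n_pools;
  if (source_pool < 0 || source_pool >= np) stop("source_pool out of range");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  Classifier cls(sigs, np, gamma);
  const R_xlen_t nr = seqs.size();

  IntegerVector n_clones(nr), support_w(nr), n_assigned(nr), n_windows(nr);
  IntegerMatrix clones_out(nr, 3);
  std::fill(clones_out.begin(), clones_out.end(), NA_INTEGER);
  // k-mer instance tallies: error_discard, assigned, unmatched, repeat_discard
  NumericVector tallies(4);

  std::unordered_map<uint64_t, MemoVal> memo;
  std::vector<int> pools_buf, cnts_buf;

  for (R_xlen_t r = 0; r < nr; ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    const int len = LENGTH(STRING_ELT(seqs, r));
    uint64_t code = 0, rc = 0;
    int valid = 0, windows = 0, assigned = 0;
    std::set<int> B;
    for (int i = 0; i < len; ++i) {
      int v = base_code(s[i]);
      if (v < 0) { valid = 0; code = 0; rc = 0; continue; }
      code = ((code << 2) | (uint64_t)v) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - v) << (2 * (k - 1)));
      if (++valid < k) continue;
      ++windows;
      uint64_t canon = std::min(code, rc);
      MemoVal mv;
      auto hit = memo.find(canon);
      if (hit != memo.end()) {
        mv = hit->second;
      } else {
        auto it = t->index.find(canon);
        if (it == t->index.end()) {
          mv.status = 0; mv.nc = 0;
        } else {
          const uint16_t* row = &t->counts[it->second * np];
          pools_buf.clear(); cnts_buf.clear();
          for (int p = 0; p < np; ++p)
            if (row[p] > 0) { pools_buf.push_back(p); cnts_buf.push_back(row[p]); }
          // if the source pool lacks this k-mer (table built elsewhere),
          // source protection simply does not apply
          int sp = (row[source_pool] > 0) ? source_pool : -1;
          ClsOut c = cls.classify(pools_buf, cnts_buf, sp);
          mv.status = (int8_t)c.status;
          mv.nc = (int8_t)c.clones.size();
          for (int q = 0; q < (int)c.clones.size(); ++q) mv.clones[q] = c.clones[q];
        }
        memo.emplace(canon, mv);
      }
      tallies[mv.status] += 1.0;
      if (mv.status == 1) {
        ++assigned;
        for (int q = 0; q < mv.nc; ++q) B.insert(mv.clones[q]);
      }
    }
    n_windows[r] = windows;
    n_assigned[r] = assigned;
    n_clones[r] = (int)B.size();
    // read signature = union of the signatures of the clones in B
    Mask u(cls.W, 0ULL);
    for (std::set<int>::iterator it = B.begin(); it != B.end(); ++it)
      for (int w = 0; w < cls.W; ++w) u[w] |= cls.masks[*it][w];
    int uw = 0;
    for (int w = 0; w < cls.W; ++w) uw += popcnt64(u[w]);
    support_w[r] = uw;
    if (B.size() >= 1 && B.size() <= 3) {
      int q = 0;
      for (std::set<int>::iterator it = B.begin(); it != B.end(); ++it)
        clones_out(r, q++) = *it;
    }
  }
  tallies.names() = CharacterVector::create("error_discard", "assigned",
                                            "unmatched", "repeat_discard");
  return List::create(_["n_clones"] = n_clones, _["clones"] = clones_out,
                      _["support_w"] = support_w, _["n_assigned"] = n_assigned,
                      _["n_windows"] = n_windows, _["kmer_tallies"] = tallies);
}

// ---------------------------------------------------------------------------
// Error-minimising subset search for pool-level marker decoding.
// Given the positive-pool set S of a marker and the signatures of candidate
// clones, finds T (1 <= |T| <= max_set) minimising |P(T) xor S|; ties broken
// by smaller |T|, then by the (lexicographic) order of the candidate rows.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".decode_search")]]
List decode_search_cpp(IntegerVector s_pools, IntegerMatrix cand_sigs,
                       int n_pools, int max_set) {
  const int nc = cand_sigs.nrow(), L = cand_sigs.ncol();
  const int W = (n_pools + 63) / 64;
  Mask S(W, 0ULL);
  for (int i = 0; i < s_pools.size(); ++i) {
    int p = s_pools[i];
    if (p < 0 || p >= n_pools) stop("pool index out of range");
    S[p >> 6] |= (1ULL << (p & 63));
  }
  std::vector<Mask> m(nc, Mask(W, 0ULL));
  for (int i = 0; i < nc; ++i)
    for (int j = 0; j < L; ++j) {
      int p = cand_sigs(i, j);
      if (p < 0 || p >= n_pools) stop("signature pool index out of range");
      m[i][p >> 6] |= (1ULL << (p & 63));
    }
  int bestE = -1;
  std::vector<int> bestT;
  Mask u(W), u2(W);
  for (int size = 1; size <= max_set && size <= nc; ++size) {
    if (size == 1) {
      for (int i = 0; i < nc; ++i) {
        int e = 0;
        for (int w = 0; w < W; ++w) e += popcnt64(m[i][w] ^ S[w]);
        if (bestE < 0 || e < bestE) { bestE = e; bestT.assign(1, i); }
      }
    } else if (size == 2) {
      for (int i = 0; i < nc; ++i)
        for (int j = i + 1; j < nc; ++j) {
          int e = 0;
          for (int w = 0; w < W; ++w)
            e += popcnt64((m[i][w] | m[j][w]) ^ S[w]);
          if (bestE < 0 || e < bestE) {
            bestE = e; bestT.resize(2); bestT[0] = i; bestT[1] = j;
          }
        }
    } else {
      for (int i = 0; i < nc; ++i) {
        for (int w = 0; w < W; ++w) u[w] = m[i][w];
        for (int j = i + 1; j < nc; ++j) {
          for (int w = 0; w < W; ++w) u2[w] = u[w] | m[j][w];
          for (int l = j + 1; l < nc; ++l) {
            int e = 0;
            for (int w = 0; w < W; ++w)
              e += popcnt64((u2[w] | m[l][w]) ^ S[w]);
            if (bestE < 0 || e < bestE) {
              bestE = e; bestT.resize(3);
              bestT[0] = i; bestT[1] = j; bestT[2] = l;
            }
          }
        }
      }
    }
  }
  return List::create(_["error"] = bestE,
                      _["members"] = IntegerVector(bestT.begin(), bestT.end()));
}
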
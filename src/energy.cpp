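#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG (splitmix64). Each permutation test derives its stream
// from a hash of (seed, segment start, segment end), so a segment's decision
// does not depend on the recursion path that reached it, and lowering the
// significance level can only remove splits, never add them.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct SegRng {
  uint64_t s;
  SegRng(uint64_t seed, uint64_t a, uint64_t b) {
    s = seed;
    splitmix64(s);
    s ^= a * 0xA24BAED4963EE407ULL;
    splitmix64(s);
    s ^= b * 0x9FB21C651E98DF25ULL;
    splitmix64(s);
  }
  uint64_t next() { return splitmix64(s); }
  // uniform integer in [0, n) via multiply-shift (n < 2^32)
  int below(uint32_t n) {
    uint32_t r = (uint32_t)(next() >> 32);
    return (int)(((uint64_t)r * n) >> 32);
  }
};

// ---------------------------------------------------------------------------
// Energy divergence between two samples (U-statistic form):
//   (|x||y|/(|x|+|y|)) * (2 E|X-Y|^a - E|X-X'|^a - E|Y-Y'|^a)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_energy_divergence(NumericVector x, NumericVector y, double alpha) {
  int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("both samples must be nonempty");
  double cross = 0.0;
  for (int i = 0; i < n; i++)
    for (int j = 0; j < m; j++)
      cross += std::pow(std::fabs(x[i] - y[j]), alpha);
  cross /= (double)n * (double)m;
  double wx = 0.0;
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++)
      wx += std::pow(std::fabs(x[i] - x[j]), alpha);
  wx = (n > 1) ? 2.0 * wx / ((double)n * (n - 1)) : 0.0;
  double wy = 0.0;
  for (int i = 0; i < m; i++)
    for (int j = i + 1; j < m; j++)
      wy += std::pow(std::fabs(y[i] - y[j]), alpha);
  wy = (m > 1) ? 2.0 * wy / ((double)m * (m - 1)) : 0.0;
  return ((double)n * m / (double)(n + m)) * (2.0 * cross - wx - wy);
}

// ---------------------------------------------------------------------------
// Fenwick (binary indexed) tree over value ranks with fused nodes (value sum
// and element count share a cache line), so that sum_i |v - x_i| over an
// incrementally built set costs O(log m) per query. Drives the alpha = 1
// best-split scan in O(m log m) per pass.
// ---------------------------------------------------------------------------

struct FenwickNode {
  double sum;
  double cnt;
};

struct Scanner {
  int m;
  std::vector<FenwickNode> tree;      // 1-based
  std::vector<int> rank;              // element -> unique rank
  std::vector<double> val;            // element values
  std::vector<double> dall;           // sum_j |val[e] - val[j]|
  std::vector<double> cL, cR;         // per-tau coefficients
  double T;                           // total pair sum
  double c0;                          // 2/m
  int lo_tau, hi_tau;                 // admissible tau range (inclusive)

  void init(const double *x, int m_, int min_size) {
    m = m_;
    tree.assign(m + 1, FenwickNode{0.0, 0.0});
    val.assign(x, x + m);
    std::vector<int> idx(m);
    for (int i = 0; i < m; i++) idx[i] = i;
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return x[a] < x[b]; });
    rank.resize(m);
    std::vector<double> prefix(m + 1, 0.0);
    for (int r = 0; r < m; r++) {
      rank[idx[r]] = r;
      prefix[r + 1] = prefix[r] + x[idx[r]];
    }
    dall.resize(m);
    T = 0.0;
    for (int e = 0; e < m; e++) {
      int r = rank[e];
      double v = x[e];
      dall[e] = ((double)r * v - prefix[r]) +
                ((prefix[m] - prefix[r + 1]) - (double)(m - r - 1) * v);
      T += dall[e];
    }
    T *= 0.5;
    c0 = 2.0 / m;
    lo_tau = min_size;
    hi_tau = m - min_size;
    cL.assign(m, 0.0);
    cR.assign(m, 0.0);
    for (int tau = lo_tau; tau <= hi_tau && tau < m; tau++) {
      double a = tau, b = m - tau;
      cL[tau] = 2.0 * b / (m * (a - 1.0));
      cR[tau] = 2.0 * a / (m * (b - 1.0));
    }
  }

  // one pass over `order`; returns max statistic over admissible taus.
  // If stop_at > -inf, returns early (with a value >= stop_at) as soon as
  // the running max reaches stop_at -- used to confirm a permutation
  // exceedance without finishing the pass.
  double scan(const std::vector<int> &order, double stop_at, int *best_tau) {
    std::fill(tree.begin(), tree.end(), FenwickNode{0.0, 0.0});
    double WL = 0.0, WR = T, sumLeft = 0.0;
    double best = R_NegInf;
    int bt = -1;
    const int last = hi_tau;
    for (int i = 0; i < m - 1; i++) {
      const int e = order[i];
      const double v = val[e];
      const int r = rank[e];
      // prefix query at rank r (ranks are unique; ties have equal values
      // so their side does not matter)
      double s = 0.0, c = 0.0;
      for (int k = r + 1; k > 0; k -= k & (-k)) {
        s += tree[k].sum;
        c += tree[k].cnt;
      }
      const double qL = (c * v - s) + ((sumLeft - s) - ((double)i - c) * v);
      WL += qL;
      WR -= (dall[e] - qL);
      for (int k = r + 1; k <= m; k += k & (-k)) {
        tree[k].sum += v;
        tree[k].cnt += 1.0;
      }
      sumLeft += v;
      const int tau = i + 1;
      if (tau >= lo_tau && tau <= last) {
        const double XC = T - WL - WR;
        const double Q = c0 * XC - cL[tau] * WL - cR[tau] * WR;
        if (Q > best) {
          best = Q;
          bt = tau;
          if (best >= stop_at) {
            if (best_tau) *best_tau = bt;
            return best;
          }
        }
      }
    }
    if (best_tau) *best_tau = bt;
    return best;
  }
};

// ---------------------------------------------------------------------------
// Single divisive step: best split of x (alpha = 1) plus a permutation test.
// Sequential stopping: the loop ends as soon as the accept/reject decision
// of the full n_perm run is determined (the exceedance count either reached
// the failure threshold, or can no longer reach it). The decision is
// identical to the full run because the permutation stream depends only on
// (seed, id_a, id_b).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_split_test(NumericVector x, int min_size, int n_perm,
                    double sig_level, double seed, double id_a, double id_b) {
  int m = x.size();
  if (m < 2 * min_size)
    return List::create(_["significant"] = false, _["tau"] = NA_INTEGER,
                        _["stat"] = NA_REAL, _["p_value"] = NA_REAL,
                        _["perms"] = 0);

  Scanner sc;
  sc.init(REAL(x), m, min_size);
  std::vector<int> order(m);
  for (int i = 0; i < m; i++) order[i] = i;
  int obs_tau = -1;
  double obs_stat = sc.scan(order, R_PosInf, &obs_tau);

  // smallest exceedance count r such that (r+1)/(n_perm+1) >= sig_level
  int kfail = (int)std::ceil(sig_level * (n_perm + 1.0) - 1.0 - 1e-9);
  if (kfail <= 0)
    return List::create(_["significant"] = false, _["tau"] = obs_tau,
                        _["stat"] = obs_stat, _["p_value"] = 1.0,
                        _["perms"] = 0);

  SegRng rng((uint64_t)(int64_t)seed, (uint64_t)(int64_t)id_a,
             (uint64_t)(int64_t)id_b);
  int exceed = 0, done = 0;
  for (int p = 0; p < n_perm; p++) {
    for (int i = m - 1; i > 0; i--) {
      int j = rng.below((uint32_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    double st = sc.scan(order, obs_stat, NULL);
    done = p + 1;
    if (st >= obs_stat) exceed++;
    if (exceed >= kfail) break;                      // cannot be significant
    if (exceed + (n_perm - done) < kfail) break;     // must be significant
  }
  bool significant = (exceed < kfail);
  double pval = (exceed + 1.0) / (done + 1.0);
  return List::create(_["significant"] = significant, _["tau"] = obs_tau,
                      _["stat"] = obs_stat, _["p_value"] = pval,
                      _["perms"] = done);
}
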
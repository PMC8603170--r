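#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cstdlib>
#include <limits>
using namespace Rcpp;

// Dynamic-programming DTW with the symmetric unit-weight step set
// {(1,0),(0,1),(1,1)}, local cost |a_i - b_j|, boundary alignment
// (1,1) -> (n,m).  `window` <= 0 means unconstrained; otherwise a
// Sakoe-Chiba band |i - j| <= window.  Costs are integer for binary
// (and any integer-valued) inputs, so the optimum is returned exactly.
// [[Rcpp::export]]
double dtw_dist_cpp(IntegerVector av, IntegerVector bv, int window = -1) {
  const int n = av.size(), m = bv.size();
  if (n == 0 || m == 0) stop("vectors must be nonempty");
  const long INF = std::numeric_limits<long>::max() / 4;
  std::vector<int> a(av.begin(), av.end()), b(bv.begin(), bv.end());
  std::vector<long> prev(m, INF), cur(m, INF);

  int w = window <= 0 ? std::max(n, m) : window;
  if (std::abs(n - m) > w)
    stop("window too small for the length difference between the vectors");

  if (window <= 0) {
    // unconstrained: tight two-row integer recurrence, no band bookkeeping
    std::vector<int> p(m), c(m);
    int acc = 0;
    for (int j = 0; j < m; ++j) { acc += std::abs(a[0] - b[j]); p[j] = acc; }
    for (int i = 1; i < n; ++i) {
      const int ai = a[i];
      int left = p[0] + std::abs(ai - b[0]);
      c[0] = left;
      for (int j = 1; j < m; ++j) {
        int best = p[j] < p[j - 1] ? p[j] : p[j - 1];
        if (left < best) best = left;
        left = best + std::abs(ai - b[j]);
        c[j] = left;
      }
      std::swap(p, c);
    }
    return (double) p[m - 1];
  }

  {
    int hi = std::min(m - 1, w);
    long acc = 0;
    for (int j = 0; j <= hi; ++j) {
      acc += std::abs(a[0] - b[j]);
      prev[j] = acc;
    }
  }
  for (int i = 1; i < n; ++i) {
    const int ai = a[i];
    const int lo = std::max(0, i - w), hi = std::min(m - 1, i + w);
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = lo; j <= hi; ++j) {
      long best = prev[j];
      if (j > 0) {
        if (prev[j - 1] < best) best = prev[j - 1];
        if (cur[j - 1] < best) best = cur[j - 1];
      }
      if (best >= INF) { cur[j] = INF; continue; }
      cur[j] = best + std::abs(ai - b[j]);
    }
    std::swap(prev, cur);
  }
  if (prev[m - 1] >= INF) stop("no feasible warping path within the window");
  return (double) prev[m - 1];
}

// Exact DTW for binary vectors in O(runs(a) * n) by collapsing the row
// dimension into constant-value bands. A monotone path crosses a band of
// k identical rows (value v) entering its first row at column j_in and
// leaving its last row at column j_out >= j_in; it visits every column
// in [j_in, j_out] at least once, plus max(0, k-1-(j_out-j_in)) repeat
// visits that can all be placed at the cheapest column of the range.
// With 0/1 column costs c_j = |v - b_j| this gives, per exit column,
//   min over j_in of  E(j_in) + sum(c[j_in..j_out])
//                       + max(0, k-1-(j_out-j_in)) * min(c[j_in..j_out])
// where E(j) = min(D_prev[j], D_prev[j-1]) is the entry value from the
// band above. Ranges containing a zero-cost column (j_in <= z_v(j_out),
// the last column with b_j == v) or wide enough for a pure diagonal
// (j_in <= j_out-k+1) drop the repeat term and reduce to a prefix-min
// scan; the remaining narrow all-mismatch ranges cost exactly k and
// reduce to a sliding-window minimum of E. Validated bit-for-bit
// against the full dynamic program on every binary pair of length <= 8
// and on randomized suites (see the test suite).
static long dtw_band_binary(const int* a, const int* b, int n) {
  const long INF = std::numeric_limits<long>::max() / 4;
  std::vector<long> P0(n + 1), P1(n + 1);
  std::vector<int> z0(n + 1), z1(n + 1);
  P0[0] = P1[0] = 0; z0[0] = z1[0] = 0;
  for (int j = 1; j <= n; ++j) {
    const int bj = b[j - 1];
    P0[j] = P0[j - 1] + (bj != 0);
    P1[j] = P1[j - 1] + (bj != 1);
    z0[j] = bj == 0 ? j : z0[j - 1];
    z1[j] = bj == 1 ? j : z1[j - 1];
  }
  std::vector<long> Dprev(n + 1, INF), Dout(n + 1, INF), E(n + 1, INF);
  std::deque<int> dq;
  bool first = true;
  int i = 0;
  while (i < n) {
    const int v = a[i];
    int k = 1;
    while (i + k < n && a[i + k] == v) ++k;
    const std::vector<long>& P = v == 0 ? P0 : P1;
    const std::vector<int>& z = v == 0 ? z0 : z1;
    if (first) {
      std::fill(E.begin(), E.end(), INF);
      E[1] = 0;                      // the path starts at cell (1,1)
    } else {
      E[1] = Dprev[1];
      for (int j = 2; j <= n; ++j) E[j] = std::min(Dprev[j], Dprev[j - 1]);
    }
    long runmin = INF;
    int mp = 0;
    dq.clear();
    for (int jo = 1; jo <= n; ++jo) {
      int M = jo - k + 1;
      if (z[jo] > M) M = z[jo];      // nondecreasing in jo
      while (mp < M) {
        ++mp;
        const long val = E[mp] >= INF ? INF : E[mp] - P[mp - 1];
        if (val < runmin) runmin = val;
      }
      long best = runmin >= INF ? INF : runmin + P[jo];
      while (!dq.empty() && E[jo] <= E[dq.back()]) dq.pop_back();
      dq.push_back(jo);
      while (!dq.empty() && dq.front() <= M) dq.pop_front();
      if (!dq.empty() && E[dq.front()] < INF) {
        const long narrow = E[dq.front()] + k;
        if (narrow < best) best = narrow;
      }
      Dout[jo] = best;
    }
    std::swap(Dprev, Dout);
    first = false;
    i += k;
  }
  return Dprev[n];
}

// [[Rcpp::export]]
double dtw_band_cpp(IntegerVector av, IntegerVector bv) {
  const int n = av.size();
  if (n == 0 || bv.size() != n) stop("equal nonzero lengths required");
  std::vector<int> a(av.begin(), av.end()), b(bv.begin(), bv.end());
  for (int t = 0; t < n; ++t) {
    if ((a[t] != 0 && a[t] != 1) || (b[t] != 0 && b[t] != 1)) {
      stop("band DTW requires binary input");
    }
  }
  return (double) dtw_band_binary(a.data(), b.data(), n);
}

static int n_one_runs(const int* x, int n) {
  int k = 0, prev = 0;
  for (int i = 0; i < n; ++i) { if (x[i] == 1 && prev == 0) ++k; prev = x[i]; }
  return k;
}

// Batched consecutive-day statistics for one interval: given the
// day-by-minute binary matrix and a list of row pairs, apply the pair
// rules (nonuse penalty for two empty days; the exact sum identity for
// one empty day; zero for two days with identical run structure up to
// warping; the full dynamic program otherwise), normalise by the mean
// daily duration, and return the mean and the penalty-pair count.
//
// The zero shortcut is exact: if both vectors start with the same value,
// end with the same value and contain the same number of 1-runs, their
// run-value sequences are identical, so mapping run i onto run i (each
// stretched or compressed freely, zeros absorbing any shift) is a
// monotone boundary-anchored warping of cost 0.
// [[Rcpp::export]]
List interval_pairs_cpp(IntegerMatrix mat, IntegerMatrix pairs,
                        double mdd, double empty_pair_k) {
  const int nd = mat.nrow(), nm = mat.ncol(), np = pairs.nrow();
  std::vector<std::vector<int>> rows(nd, std::vector<int>(nm));
  std::vector<int> sums(nd, 0), runs(nd, 0);
  for (int d = 0; d < nd; ++d) {
    int s = 0;
    for (int m = 0; m < nm; ++m) {
      int x = mat(d, m);
      if (x != 0 && x != 1) stop("day vectors must be binary");
      rows[d][m] = x;
      s += x;
    }
    sums[d] = s;
    runs[d] = n_one_runs(rows[d].data(), nm);
  }
  double total = 0;
  int pen = 0;
  for (int r = 0; r < np; ++r) {
    const int i = pairs(r, 0) - 1, j = pairs(r, 1) - 1;
    if (i < 0 || i >= nd || j < 0 || j >= nd) stop("pair index out of range");
    double raw;
    if (sums[i] == 0 && sums[j] == 0) {
      raw = empty_pair_k * mdd;
      ++pen;
    } else if (sums[i] == 0 || sums[j] == 0) {
      raw = (double) std::max(sums[i], sums[j]);
      ++pen;
    } else if (runs[i] == runs[j] &&
               rows[i][0] == rows[j][0] &&
               rows[i][nm - 1] == rows[j][nm - 1]) {
      raw = 0.0;
    } else {
      raw = (double) dtw_band_binary(rows[i].data(), rows[j].data(), nm);
    }
    total += mdd > 0 ? raw / mdd : 0.0;
  }
  return List::create(Named("mean") = total / np,
                      Named("n_penalty") = pen);
}

// Exhaustive depth-first enumeration of every monotone warping path from
// (1,1) to (n,m); returns the minimum cumulative cost.  Independent of
// the dynamic program above (no memoisation); exponential, intended for
// short vectors only.
static long enum_rec(const std::vector<int>& a, const std::vector<int>& b,
                     int i, int j, long acc) {
  acc += std::abs(a[i] - b[j]);
  const int n = (int) a.size(), m = (int) b.size();
  if (i == n - 1 && j == m - 1) return acc;
  long best = std::numeric_limits<long>::max();
  if (i + 1 < n) {
    long v = enum_rec(a, b, i + 1, j, acc);
    if (v < best) best = v;
  }
  if (j + 1 < m) {
    long v = enum_rec(a, b, i, j + 1, acc);
    if (v < best) best = v;
  }
  if (i + 1 < n && j + 1 < m) {
    long v = enum_rec(a, b, i + 1, j + 1, acc);
    if (v < best) best = v;
  }
  return best;
}

// [[Rcpp::export]]
double dtw_enum_cpp(IntegerVector av, IntegerVector bv) {
  const int n = av.size(), m = bv.size();
  if (n == 0 || m == 0) stop("vectors must be nonempty");
  if (n > 12 || m > 12) stop("path enumeration is limited to length <= 12");
  std::vector<int> a(av.begin(), av.end()), b(bv.begin(), bv.end());
  return (double) enum_rec(a, b, 0, 0, 0L);
}
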
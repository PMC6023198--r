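#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Local cost between two scalar samples: |q - c| by default, squared
// difference when squared = true.
static inline double local_cost(double a, double b, bool squared) {
  double d = a - b;
  return squared ? d * d : std::fabs(d);
}

// DTW distance under the classic recurrence
//   g(i,j) = d(q_i, c_j) + min(g(i-1,j-1), g(i-1,j), g(i,j-1))
// with g(1,1) = d(q_1, c_1); rolling two-row dynamic programme.
static double dtw_dist_raw(const double* q, int n, const double* c, int m,
                           bool squared, std::vector<double>& prev,
                           std::vector<double>& cur) {
  prev.resize(m); cur.resize(m);
  prev[0] = local_cost(q[0], c[0], squared);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + local_cost(q[0], c[j], squared);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + local_cost(q[i], c[0], squared);
    for (int j = 1; j < m; ++j) {
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = best + local_cost(q[i], c[j], squared);
    }
    prev.swap(cur);
  }
  return prev[m - 1];
}

// Full cumulative-cost matrix (row-major n x m) for path backtracking.
static void dtw_full(const double* q, int n, const double* c, int m,
                     bool squared, std::vector<double>& g) {
  g.resize((size_t)n * m);
  g[0] = local_cost(q[0], c[0], squared);
  for (int j = 1; j < m; ++j) g[j] = g[j - 1] + local_cost(q[0], c[j], squared);
  for (int i = 1; i < n; ++i) {
    double* row = &g[(size_t)i * m];
    double* up = &g[(size_t)(i - 1) * m];
    row[0] = up[0] + local_cost(q[i], c[0], squared);
    for (int j = 1; j < m; ++j) {
      double best = up[j - 1];
      if (up[j] < best) best = up[j];
      if (row[j - 1] < best) best = row[j - 1];
      row[j] = best + local_cost(q[i], c[j], squared);
    }
  }
}

// Backtrack the optimal path; appends (i, j) pairs (0-based) in reverse.
static void dtw_backtrack(const std::vector<double>& g, int n, int m,
                          std::vector<std::pair<int, int> >& rev) {
  rev.clear();
  int i = n - 1, j = m - 1;
  rev.push_back(std::make_pair(i, j));
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double diag = g[(size_t)(i - 1) * m + j - 1];
      double up = g[(size_t)(i - 1) * m + j];
      double left = g[(size_t)i * m + j - 1];
      if (diag <= up && diag <= left) { --i; --j; }
      else if (up <= left) { --i; }
      else { --j; }
    }
    rev.push_back(std::make_pair(i, j));
  }
}

// [[Rcpp::export(name = ".cpp_dtw")]]
double cpp_dtw(NumericVector q, NumericVector c, bool squared = false) {
  if (q.size() == 0 || c.size() == 0) stop("empty series");
  std::vector<double> a, b;
  return dtw_dist_raw(REAL(q), q.size(), REAL(c), c.size(), squared, a, b);
}

// Pairwise DTW distances between rows of X (V x T) and rows of C (k x T).
// [[Rcpp::export(name = ".cpp_dtw_matrix")]]
NumericMatrix cpp_dtw_matrix(NumericMatrix X, NumericMatrix C,
                             bool squared = false) {
  const int V = X.nrow(), K = C.nrow(), Tx = X.ncol(), Tc = C.ncol();
  NumericMatrix D(V, K);
  std::vector<double> q(Tx), ck(Tc), a, b;
  for (int k = 0; k < K; ++k) {
    for (int t = 0; t < Tc; ++t) ck[t] = C(k, t);
    for (int v = 0; v < V; ++v) {
      for (int t = 0; t < Tx; ++t) q[t] = X(v, t);
      D(v, k) = dtw_dist_raw(&q[0], Tx, &ck[0], Tc, squared, a, b);
    }
  }
  return D;
}

// Optimal warping path (1-based index pairs from (1,1) to (n,m)).
// [[Rcpp::export(name = ".cpp_dtw_path")]]
IntegerMatrix cpp_dtw_path(NumericVector q, NumericVector c,
                           bool squared = false) {
  if (q.size() == 0 || c.size() == 0) stop("empty series");
  const int n = q.size(), m = c.size();
  std::vector<double> g;
  dtw_full(REAL(q), n, REAL(c), m, squared, g);
  std::vector<std::pair<int, int> > rev;
  dtw_backtrack(g, n, m, rev);
  IntegerMatrix path(rev.size(), 2);
  for (size_t r = 0; r < rev.size(); ++r) {
    path(rev.size() - 1 - r, 0) = rev[r].first + 1;
    path(rev.size() - 1 - r, 1) = rev[r].second + 1;
  }
  return path;
}

// One DTW-barycenter-averaging (DBA) pass: align every row of X to the
// current centroid and average the samples mapped onto each centroid
// index. Returns the updated centroid (length T).
// [[Rcpp::export(name = ".cpp_dba_update")]]
NumericVector cpp_dba_update(NumericMatrix X, NumericVector centroid,
                             bool squared = false) {
  const int V = X.nrow(), Tx = X.ncol(), T = centroid.size();
  std::vector<double> sum(T, 0.0);
  std::vector<int> count(T, 0);
  std::vector<double> q(Tx), g;
  std::vector<std::pair<int, int> > rev;
  const double* cen = REAL(centroid);
  for (int v = 0; v < V; ++v) {
    for (int t = 0; t < Tx; ++t) q[t] = X(v, t);
    dtw_full(&q[0], Tx, cen, T, squared, g);
    dtw_backtrack(g, Tx, T, rev);
    for (size_t r = 0; r < rev.size(); ++r) {
      sum[rev[r].second] += q[rev[r].first];
      count[rev[r].second] += 1;
    }
  }
  NumericVector out(T);
  for (int t = 0; t < T; ++t)
    out[t] = count[t] > 0 ? sum[t] / count[t] : centroid[t];
  return out;
}
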
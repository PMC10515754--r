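#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming alignment cost over a local cost matrix with the
// symmetric step pattern {(1,0),(0,1),(1,1)}, boundary-aligned ends.
static NumericMatrix accumulate(const NumericMatrix& cost) {
  const int n = cost.nrow(), m = cost.ncol();
  NumericMatrix D(n, m);
  D(0, 0) = cost(0, 0);
  for (int i = 1; i < n; ++i) D(i, 0) = D(i - 1, 0) + cost(i, 0);
  for (int j = 1; j < m; ++j) D(0, j) = D(0, j - 1) + cost(0, j);
  for (int i = 1; i < n; ++i)
    for (int j = 1; j < m; ++j) {
      double best = D(i - 1, j - 1);
      if (D(i - 1, j) < best) best = D(i - 1, j);
      if (D(i, j - 1) < best) best = D(i, j - 1);
      D(i, j) = cost(i, j) + best;
    }
  return D;
}

// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  NumericMatrix D = accumulate(cost);
  // backtrack the lowest-cost path; diagonal preferred on ties so that
  // identical series yield the diagonal path
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    if (i == 0) --j;
    else if (j == 0) --i;
    else {
      double d = D(i - 1, j - 1), u = D(i - 1, j), l = D(i, j - 1);
      if (d <= u && d <= l) { --i; --j; }
      else if (u <= l) --i;
      else --j;
    }
    pi.push_back(i); pj.push_back(j);
  }
  const int len = pi.size();
  IntegerMatrix path(len, 2);
  for (int k = 0; k < len; ++k) {       // reverse to start at (1,1)
    path(k, 0) = pi[len - 1 - k] + 1;
    path(k, 1) = pj[len - 1 - k] + 1;
  }
  return List::create(_["total_cost"] = D(n - 1, m - 1), _["path"] = path);
}

// Pairwise DTW total costs for rows of a series matrix (univariate
// series, absolute-difference local cost).
// [[Rcpp::export(name = ".dtw_pairwise")]]
NumericMatrix dtw_pairwise(NumericMatrix series) {
  const int k = series.nrow(), T = series.ncol();
  NumericMatrix out(k, k);
  NumericMatrix cost(T, T);
  for (int a = 0; a < k; ++a)
    for (int b = a + 1; b < k; ++b) {
      for (int i = 0; i < T; ++i)
        for (int j = 0; j < T; ++j)
          cost(i, j) = std::abs(series(a, i) - series(b, j));
      NumericMatrix D = accumulate(cost);
      out(a, b) = out(b, a) = D(T - 1, T - 1);
    }
  return out;
}
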
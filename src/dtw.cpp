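#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping under the symmetric2 step pattern: a diagonal step
// accumulates twice the local cost, horizontal/vertical steps accumulate it
// once. Local cost is the absolute difference of the two values. The first
// cell is charged as a diagonal entry (weight 2); this constant offset is
// shared by every admissible path and does not affect the optimum.
//
// Backtrace tie-break (matters because truncation depends on the exact path
// chosen among cost-equal optima): prefer the diagonal predecessor, then the
// predecessor that advances the query, then the one advancing the reference.
//
// [[Rcpp::export]]
List dtw_core(NumericVector q, NumericVector r) {
  const int n = q.size(), m = r.size();
  if (n < 2 || m < 2) stop("series must have at least 2 points");
  NumericMatrix D(n, m);

  D(0, 0) = 2.0 * std::abs(q[0] - r[0]);
  for (int i = 1; i < n; ++i) D(i, 0) = D(i - 1, 0) + std::abs(q[i] - r[0]);
  for (int j = 1; j < m; ++j) D(0, j) = D(0, j - 1) + std::abs(q[0] - r[j]);
  for (int i = 1; i < n; ++i) {
    for (int j = 1; j < m; ++j) {
      const double d = std::abs(q[i] - r[j]);
      double best = D(i - 1, j - 1) + 2.0 * d;          // diagonal
      const double up = D(i - 1, j) + d;                // advance query
      const double left = D(i, j - 1) + d;              // advance reference
      if (up < best) best = up;
      if (left < best) best = left;
      D(i, j) = best;
    }
  }

  // Backtrace from (n-1, m-1); path length is at most n + m - 1.
  std::vector<int> qi, ri;
  int i = n - 1, j = m - 1;
  qi.push_back(i); ri.push_back(j);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      const double d = std::abs(q[i] - r[j]);
      const double cur = D(i, j);
      if (cur == D(i - 1, j - 1) + 2.0 * d) { --i; --j; }
      else if (cur == D(i - 1, j) + d) { --i; }
      else { --j; }
    }
    qi.push_back(i); ri.push_back(j);
  }

  const int k = qi.size();
  IntegerMatrix path(k, 2);
  for (int s = 0; s < k; ++s) {          // reverse into 1-based indices
    path(s, 0) = qi[k - 1 - s] + 1;
    path(s, 1) = ri[k - 1 - s] + 1;
  }
  return List::create(_["path"] = path, _["distance"] = D(n - 1, m - 1));
}
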
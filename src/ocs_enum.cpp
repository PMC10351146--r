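#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive search over k-subsets of n candidates for cardinality-fixed OCS.
// Contributions: each selected bull 1/(2k), pseudofemale (last row/col of R)
// 1/2.  Maximizes the contribution-weighted GEBV subject to c'Rc <= C; also
// tracks the minimum-c'Rc subset for the infeasible fallback.  Ties in the
// objective are broken toward the lexicographically smallest subset (the
// enumeration order), making the result deterministic.

// [[Rcpp::export]]
List cpp_enum_ocs(NumericVector a, NumericMatrix R, int k, double C) {
  int n = a.size();
  if (R.nrow() != n + 1) stop("R must be (n+1) x (n+1) with the pseudofemale last");
  double cb = 1.0 / (2.0 * k);
  double base = 0.25 * R(n, n);
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  double best_obj = R_NegInf, best_q = NA_REAL;
  double min_q = R_PosInf, min_q_obj = NA_REAL;
  std::vector<int> best(k, -1), minq(k, -1);
  while (true) {
    double quad = base, obj = 0.0;
    for (int i = 0; i < k; ++i) {
      obj += a[idx[i]];
      quad += 2.0 * cb * 0.5 * R(idx[i], n) + cb * cb * R(idx[i], idx[i]);
      for (int j = 0; j < i; ++j) quad += 2.0 * cb * cb * R(idx[i], idx[j]);
    }
    obj *= cb;
    if (quad <= C && obj > best_obj) { best_obj = obj; best_q = quad; best = idx; }
    if (quad < min_q) { min_q = quad; min_q_obj = obj; minq = idx; }
    // next combination
    int i = k - 1;
    while (i >= 0 && idx[i] == n - k + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  }
  IntegerVector bi(k), mi(k);
  bool feasible = best[0] >= 0;
  for (int i = 0; i < k; ++i) { bi[i] = best[i] + 1; mi[i] = minq[i] + 1; }
  return List::create(_["feasible"] = feasible,
                      _["selected"] = feasible ? bi : IntegerVector(0),
                      _["objective"] = best_obj, _["quad"] = best_q,
                      _["minq_selected"] = mi, _["minq"] = min_q,
                      _["minq_objective"] = min_q_obj);
}
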
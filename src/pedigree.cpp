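#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Pedigree algebra.  Animals are coded 1..n with 0 = unknown parent and
// parents preceding offspring.  F is the inbreeding coefficient and
// D the Mendelian-sampling variance scale d_i = 0.5 - 0.25 (F_s + F_d)
// with F = -1 for an unknown parent (giving 1 and 0.75 for the
// zero/one-known-parent cases).

static void check_sorted(const IntegerVector& sire, const IntegerVector& dam) {
  int n = sire.size();
  for (int i = 0; i < n; ++i) {
    if (sire[i] > i || dam[i] > i)
      stop("pedigree not sorted: parents must precede offspring");
    if (sire[i] < 0 || dam[i] < 0) stop("negative parent code");
  }
}

// A %*% v via Colleau's indirect method, pedigree restricted to 1..m
static void a_times(const IntegerVector& sire, const IntegerVector& dam,
                    const std::vector<double>& D, int m,
                    std::vector<double>& u /* in: v, out: A v */) {
  for (int c = m - 1; c >= 0; --c) {
    if (u[c] != 0.0) {
      if (sire[c] > 0) u[sire[c] - 1] += 0.5 * u[c];
      if (dam[c] > 0) u[dam[c] - 1] += 0.5 * u[c];
    }
  }
  for (int j = 0; j < m; ++j) u[j] *= D[j];
  // forward pass: a_j = w_j + 0.5 (a_s + a_d); w currently stored in u
  for (int j = 0; j < m; ++j) {
    double a = u[j];
    if (sire[j] > 0) a += 0.5 * u[sire[j] - 1];
    if (dam[j] > 0) a += 0.5 * u[dam[j] - 1];
    u[j] = a;
  }
}

// [[Rcpp::export]]
List cpp_ped_fd(IntegerVector sire, IntegerVector dam, NumericVector F_init) {
  check_sorted(sire, dam);
  int n = sire.size(), n0 = F_init.size();
  std::vector<double> F(n), D(n);
  std::vector<double> u;
  for (int i = 0; i < n; ++i) {
    if (i < n0) {
      F[i] = F_init[i];
    } else if (sire[i] == 0 || dam[i] == 0) {
      F[i] = 0.0;
    } else {
      // F_i = A[s, d] / 2 over the pedigree 1..i
      u.assign(i, 0.0);
      u[dam[i] - 1] = 1.0;
      a_times(sire, dam, D, i, u);
      F[i] = 0.5 * u[sire[i] - 1];
    }
    double fs = sire[i] > 0 ? F[sire[i] - 1] : -1.0;
    double fd = dam[i] > 0 ? F[dam[i] - 1] : -1.0;
    D[i] = 0.5 - 0.25 * (fs + fd);
  }
  return List::create(_["F"] = NumericVector(F.begin(), F.end()),
                      _["D"] = NumericVector(D.begin(), D.end()));
}

// [[Rcpp::export]]
NumericMatrix cpp_a_block(IntegerVector sire, IntegerVector dam,
                          NumericVector D, IntegerVector idx) {
  check_sorted(sire, dam);
  int n = sire.size(), k = idx.size();
  std::vector<double> Dv(D.begin(), D.end());
  NumericMatrix out(k, k);
  std::vector<double> u;
  for (int c = 0; c < k; ++c) {
    u.assign(n, 0.0);
    u[idx[c] - 1] = 1.0;
    a_times(sire, dam, Dv, n, u);
    for (int r = 0; r < k; ++r) out(r, c) = u[idx[r] - 1];
  }
  // enforce exact symmetry (averages out round-off)
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < i; ++j) {
      double v = 0.5 * (out(i, j) + out(j, i));
      out(i, j) = v; out(j, i) = v;
    }
  return out;
}

// [[Rcpp::export]]
List cpp_ainv_triplets(IntegerVector sire, IntegerVector dam, NumericVector D) {
  check_sorted(sire, dam);
  int n = sire.size();
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(9 * n); tj.reserve(9 * n); tx.reserve(9 * n);
  for (int i = 0; i < n; ++i) {
    double al = 1.0 / D[i];
    int s = sire[i], d = dam[i];
    ti.push_back(i + 1); tj.push_back(i + 1); tx.push_back(al);
    if (s > 0) {
      ti.push_back(i + 1); tj.push_back(s); tx.push_back(-0.5 * al);
      ti.push_back(s); tj.push_back(i + 1); tx.push_back(-0.5 * al);
      ti.push_back(s); tj.push_back(s); tx.push_back(0.25 * al);
    }
    if (d > 0) {
      ti.push_back(i + 1); tj.push_back(d); tx.push_back(-0.5 * al);
      ti.push_back(d); tj.push_back(i + 1); tx.push_back(-0.5 * al);
      ti.push_back(d); tj.push_back(d); tx.push_back(0.25 * al);
    }
    if (s > 0 && d > 0) {
      ti.push_back(s); tj.push_back(d); tx.push_back(0.25 * al);
      ti.push_back(d); tj.push_back(s); tx.push_back(0.25 * al);
    }
  }
  return List::create(_["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()));
}

// [[Rcpp::export]]
NumericMatrix cpp_nrm(IntegerVector sire, IntegerVector dam) {
  // tabular method: A_ii = 1 + A_sd / 2, A_ij = (A_js + A_jd) / 2
  check_sorted(sire, dam);
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s > 0) v += 0.5 * A(j, s - 1);
      if (d > 0) v += 0.5 * A(j, d - 1);
      A(i, j) = v; A(j, i) = v;
    }
    A(i, i) = 1.0 + (s > 0 && d > 0 ? 0.5 * A(s - 1, d - 1) : 0.0);
  }
  return A;
}
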
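#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Historical Wright-Fisher population: discrete generations, dioecious with
// a 1:1 sex ratio (males are the first half of each cohort), random mating,
// Poisson(1/Morgan) recombination, recurrent symmetric mutation (allele state
// flipped with probability mu per transmitted allele).  Alleles only; founder
// segment provenance starts at the expanded base cohort, not here.

static void wf_gamete(const unsigned char* h0, const unsigned char* h1,
                      const NumericVector& pos, const IntegerVector& chr_first,
                      const NumericVector& chr_lo, const NumericVector& chr_hi,
                      double mu, int L, unsigned char* out) {
  int n_chr = chr_lo.size();
  std::vector<double> cx;
  for (int c = 0; c < n_chr; ++c) {
    double lo = chr_lo[c], hi = chr_hi[c];
    int ncx = (int) R::rpois(hi - lo);
    cx.clear();
    for (int i = 0; i < ncx; ++i) cx.push_back(lo + unif_rand() * (hi - lo));
    std::sort(cx.begin(), cx.end());
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int i0 = chr_first[c], i1 = chr_first[c + 1];
    double a = lo;
    int li = i0;
    for (int k = 0; k <= ncx; ++k) {
      double b = (k < ncx) ? cx[k] : hi;
      if (b > a) {
        const double* pbeg = pos.begin();
        int lj = (int)(std::upper_bound(pbeg + li, pbeg + i1, b) - pbeg);
        const unsigned char* src = cur == 0 ? h0 : h1;
        std::copy(src + li, src + lj, out + li);
        li = lj;
        a = b;
      }
      cur = 1 - cur;
    }
  }
  if (mu > 0) {
    int nmut = (int) R::rbinom((double) L, mu);
    for (int i = 0; i < nmut; ++i) {
      int l = (int)(unif_rand() * L);
      if (l >= L) l = L - 1;
      out[l] = 1 - out[l];
    }
  }
}

// [[Rcpp::export]]
List cpp_wright_fisher(NumericVector pos, IntegerVector chr_first,
                       NumericVector chr_lo, NumericVector chr_hi,
                       IntegerVector sizes, double mu, int n_final) {
  int L = pos.size();
  int n_gen = sizes.size();
  int nmax = n_final;
  for (int g = 0; g < n_gen; ++g) nmax = std::max(nmax, sizes[g]);
  std::vector<unsigned char> cur((size_t)2 * nmax * L), nxt((size_t)2 * nmax * L);

  int N = sizes[0];
  for (size_t i = 0; i < (size_t)2 * N * L; ++i) cur[i] = unif_rand() < 0.5 ? 1 : 0;
  NumericVector p0(L);
  for (int ind = 0; ind < 2 * N; ++ind)
    for (int l = 0; l < L; ++l) p0[l] += cur[(size_t)ind * L + l];
  for (int l = 0; l < L; ++l) p0[l] /= 2.0 * N;

  for (int g = 1; g <= n_gen; ++g) {
    int M = (g < n_gen) ? sizes[g] : n_final;  // past the trajectory: base expansion
    int n_m = N / 2;                           // sires: first half of parents
    for (int o = 0; o < M; ++o) {
      int s = (int)(unif_rand() * n_m); if (s >= n_m) s = n_m - 1;
      int d = n_m + (int)(unif_rand() * (N - n_m)); if (d >= N) d = N - 1;
      wf_gamete(&cur[(size_t)2 * s * L], &cur[((size_t)2 * s + 1) * L],
                pos, chr_first, chr_lo, chr_hi, mu, L, &nxt[(size_t)2 * o * L]);
      wf_gamete(&cur[(size_t)2 * d * L], &cur[((size_t)2 * d + 1) * L],
                pos, chr_first, chr_lo, chr_hi, mu, L, &nxt[((size_t)2 * o + 1) * L]);
    }
    std::swap(cur, nxt);
    N = M;
  }

  IntegerMatrix hap(L, 2 * n_final);
  for (int h = 0; h < 2 * n_final; ++h)
    for (int l = 0; l < L; ++l) hap(l, h) = cur[(size_t)h * L + l];
  return List::create(_["hap"] = hap, _["p0"] = p0);
}
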
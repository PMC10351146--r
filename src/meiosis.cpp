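#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gamete formation with founder-segment provenance.
//
// A haplotype is (i) an allele vector over all loci and (ii) a segment list
// covering the genome in global genetic coordinates (Morgan, chromosomes laid
// end to end): columns (end, founder_label), rows sorted by end, last end ==
// genome length.  Crossover counts per chromosome are Poisson(length in
// Morgan), positions uniform, starting parental haplotype fair; no crossover
// interference, no obligate chiasma, no mutation (breeding phase only).

static void splice_segments(const NumericMatrix& seg, double a, double b,
                            std::vector<double>& out_end,
                            std::vector<double>& out_lab) {
  // append the part of `seg` overlapping (a, b], merging equal labels
  int ns = seg.nrow();
  // first segment with end > a
  int lo = 0, hi = ns;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (seg(mid, 0) > a) hi = mid; else lo = mid + 1;
  }
  for (int s = lo; s < ns; ++s) {
    double end = std::min(seg(s, 0), b);
    double lab = seg(s, 1);
    if (end > a) {
      if (!out_lab.empty() && out_lab.back() == lab) {
        out_end.back() = end;  // merge
      } else {
        out_end.push_back(end);
        out_lab.push_back(lab);
      }
    }
    if (seg(s, 0) >= b) break;
  }
}

// one gamete from parent haplotypes h0/h1 (allele pointers) + segment lists
static void make_gamete(const int* h0, const int* h1,
                        const NumericMatrix& seg0, const NumericMatrix& seg1,
                        const NumericVector& pos,
                        const IntegerVector& chr_first,  // 0-based first locus per chrom, plus L sentinel
                        const NumericVector& chr_lo, const NumericVector& chr_hi,
                        int* out_alleles,
                        std::vector<double>& out_end,
                        std::vector<double>& out_lab) {
  int n_chr = chr_lo.size();
  out_end.clear();
  out_lab.clear();
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
    int li = i0;  // next locus to fill
    for (int k = 0; k <= ncx; ++k) {
      double b = (k < ncx) ? cx[k] : hi;
      if (b > a) {
        // loci in (a, b]
        const double* pbeg = pos.begin();
        int lj = (int)(std::upper_bound(pbeg + li, pbeg + i1, b) - pbeg);
        const int* src = cur == 0 ? h0 : h1;
        for (int l = li; l < lj; ++l) out_alleles[l] = src[l];
        li = lj;
        splice_segments(cur == 0 ? seg0 : seg1, a, b, out_end, out_lab);
        a = b;
      }
      cur = 1 - cur;
    }
  }
}

// [[Rcpp::export]]
List cpp_meiose(IntegerMatrix hap, List segs,
                NumericVector pos, IntegerVector chr_first,
                NumericVector chr_lo, NumericVector chr_hi) {
  int L = hap.nrow();
  IntegerVector alleles(L);
  std::vector<double> oe, ol;
  NumericMatrix s0 = segs[0], s1 = segs[1];
  make_gamete(&hap(0, 0), &hap(0, 1), s0, s1, pos, chr_first, chr_lo, chr_hi,
              alleles.begin(), oe, ol);
  int ns = oe.size();
  NumericMatrix seg(ns, 2);
  for (int s = 0; s < ns; ++s) { seg(s, 0) = oe[s]; seg(s, 1) = ol[s]; }
  return List::create(_["alleles"] = alleles, _["seg"] = seg);
}

// [[Rcpp::export]]
List cpp_mate(IntegerMatrix hap, List segs,
              IntegerVector sire, IntegerVector dam,
              NumericVector pos, IntegerVector chr_first,
              NumericVector chr_lo, NumericVector chr_hi) {
  int L = hap.nrow();
  int n_off = sire.size();
  IntegerMatrix out(L, 2 * n_off);
  List out_segs(2 * n_off);
  std::vector<double> oe, ol;
  for (int o = 0; o < n_off; ++o) {
    for (int side = 0; side < 2; ++side) {
      int par = (side == 0 ? sire[o] : dam[o]) - 1;  // 1-based in
      NumericMatrix s0 = segs[2 * par], s1 = segs[2 * par + 1];
      make_gamete(&hap(0, 2 * par), &hap(0, 2 * par + 1), s0, s1,
                  pos, chr_first, chr_lo, chr_hi,
                  &out(0, 2 * o + side), oe, ol);
      int ns = oe.size();
      NumericMatrix seg(ns, 2);
      for (int s = 0; s < ns; ++s) { seg(s, 0) = oe[s]; seg(s, 1) = ol[s]; }
      out_segs[2 * o + side] = seg;
    }
  }
  return List::create(_["hap"] = out, _["segs"] = out_segs);
}

// shared genome length (same founder label) between two segment lists
static double shared_len(const NumericMatrix& a, const NumericMatrix& b) {
  int ia = 0, ib = 0, na = a.nrow(), nb = b.nrow();
  double prev = 0.0, tot = 0.0;
  while (ia < na && ib < nb) {
    double ea = a(ia, 0), eb = b(ib, 0);
    double end = std::min(ea, eb);
    if (a(ia, 1) == b(ib, 1)) tot += end - prev;
    prev = end;
    if (ea <= end) ++ia;
    if (eb <= end) ++ib;
  }
  return tot;
}

// [[Rcpp::export]]
NumericVector cpp_ibd_pairs(List segs, IntegerMatrix pairs, double glen) {
  // kinship f of pair (i, j): 1/4 sum over the four haplotype pairings of the
  // shared-founder-segment genome fraction; i == j gives the self-kinship
  int np = pairs.nrow();
  NumericVector f(np);
  for (int p = 0; p < np; ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    NumericMatrix a0 = segs[2 * i], a1 = segs[2 * i + 1];
    NumericMatrix b0 = segs[2 * j], b1 = segs[2 * j + 1];
    f[p] = 0.25 * (shared_len(a0, b0) + shared_len(a0, b1) +
                   shared_len(a1, b0) + shared_len(a1, b1)) / glen;
  }
  return f;
}
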
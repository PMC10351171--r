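#include <Rcpp.h>
using namespace Rcpp;

// Batch gamete sampler. Crossovers per chromosome ~ Poisson(length in
// Morgans), breakpoints uniform (no interference); independent assortment
// across chromosomes; recurrent mutation as allele flip. Uses R's RNG so
// results are reproducible under set.seed().
//
// h1, h2:      parent haplotypes (individuals x loci, 0/1)
// parent_row:  1-based row of the parent contributing each gamete
// chr_start/chr_end: 1-based locus index range of each chromosome
// pos:         chromosome-local genetic position in Morgans per locus
// chr_len:     chromosome length in Morgans
// [[Rcpp::export]]
IntegerMatrix cpp_make_gametes(const IntegerMatrix& h1, const IntegerMatrix& h2,
                               const IntegerVector& parent_row,
                               const IntegerVector& chr_start,
                               const IntegerVector& chr_end,
                               const NumericVector& pos,
                               const NumericVector& chr_len,
                               double mut_rate) {
  const int m = h1.ncol();
  const int ng = parent_row.size();
  const int nchr = chr_start.size();
  IntegerMatrix out(ng, m);
  std::vector<double> bp;
  for (int g = 0; g < ng; ++g) {
    const int pr = parent_row[g] - 1;
    for (int c = 0; c < nchr; ++c) {
      const int s = chr_start[c] - 1;
      const int e = chr_end[c] - 1;
      const double L = chr_len[c];
      int cur = (unif_rand() < 0.5) ? 1 : 0;
      int k = (L > 0.0) ? (int) R::rpois(L) : 0;
      if (s > e) continue;
      if (k == 0) {
        for (int j = s; j <= e; ++j)
          out(g, j) = cur ? h2(pr, j) : h1(pr, j);
      } else {
        bp.resize(k);
        for (int b = 0; b < k; ++b) bp[b] = unif_rand() * L;
        std::sort(bp.begin(), bp.end());
        int bi = 0;
        for (int j = s; j <= e; ++j) {
          while (bi < k && bp[bi] <= pos[j]) { cur ^= 1; ++bi; }
          out(g, j) = cur ? h2(pr, j) : h1(pr, j);
        }
      }
    }
    if (mut_rate > 0.0) {
      int nmut = (int) R::rbinom((double) m, mut_rate);
      for (int t = 0; t < nmut; ++t) {
        int j = (int) std::floor(unif_rand() * m);
        if (j >= m) j = m - 1;
        out(g, j) = 1 - out(g, j);
      }
    }
  }
  return out;
}

// Wright's numerator relationship matrix by the recursive tabular method.
// sire/dam are 1-based row indices into the (topologically ordered)
// pedigree, 0 for unknown. Inbreeding enters through 0.5 * a(s, d).
// [[Rcpp::export]]
NumericMatrix cpp_tabular_A(const IntegerVector& sire, const IntegerVector& dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int j = 0; j < n; ++j) {
    const int s = sire[j] - 1;
    const int d = dam[j] - 1;
    for (int i = 0; i < j; ++i) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(i, s);
      if (d >= 0) v += 0.5 * A(i, d);
      A(i, j) = v;
      A(j, i) = v;
    }
    double dg = 1.0;
    if (s >= 0 && d >= 0) dg += 0.5 * A(s, d);
    A(j, j) = dg;
  }
  return A;
}
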
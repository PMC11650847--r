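#include <Rcpp.h>
using namespace Rcpp;

// Tabular (recursive) numerator relationship matrix.
// `sire`/`dam` are 0-based indices into a topologically ordered pedigree
// (parents strictly before offspring); -1 marks an unknown parent side.
// Returns the full n x n A matrix, diagonal 1 + F_i.
// [[Rcpp::export]]
NumericMatrix cpp_tabular_a(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s >= i || d >= i) stop("pedigree not topologically ordered");
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(j, s);
      if (d >= 0) a += 0.5 * A(j, d);
      A(j, i) = a;
      A(i, j) = a;
    }
    double f = (s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0;
    A(i, i) = 1.0 + f;
  }
  return A;
}

// Gene dropping: one biallelic locus dropped through a topologically
// ordered pedigree, nrep independent replicates. An unknown parent side
// draws a fresh founder allele (carrier with probability `maf`), i.e. a
// unique phantom founder. Uses R's RNG so results are reproducible under
// set.seed(). Returns dosages (carrier-allele counts), animals x nrep.
// [[Rcpp::export]]
IntegerMatrix cpp_gene_drop(IntegerVector sire, IntegerVector dam,
                            double maf, int nrep) {
  int n = sire.size();
  IntegerMatrix D(n, nrep);
  std::vector<int> a1(n), a2(n);
  RNGScope scope;
  for (int r = 0; r < nrep; ++r) {
    for (int i = 0; i < n; ++i) {
      int s = sire[i], d = dam[i];
      int x = (s >= 0) ? ((unif_rand() < 0.5) ? a1[s] : a2[s])
                       : ((unif_rand() < maf) ? 1 : 0);
      int y = (d >= 0) ? ((unif_rand() < 0.5) ? a1[d] : a2[d])
                       : ((unif_rand() < maf) ? 1 : 0);
      a1[i] = x;
      a2[i] = y;
      D(i, r) = x + y;
    }
  }
  return D;
}
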
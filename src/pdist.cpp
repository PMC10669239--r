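#include <Rcpp.h>
using namespace Rcpp;

// Pairwise mismatch / comparable-column counts over an integer-encoded
// alignment (rows = sequences). Code 0 marks a non-comparable state (gap,
// X, B, Z); codes 1..20 are the amino acids (U already folded into C).
// [[Rcpp::export(name = ".pdist_counts")]]
List pdist_counts(IntegerMatrix codes) {
  const int n = codes.nrow(), L = codes.ncol();
  NumericMatrix mism(n, n), comp(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int m = 0, c = 0;
      for (int s = 0; s < L; ++s) {
        const int a = codes(i, s), b = codes(j, s);
        if (a > 0 && b > 0) {
          ++c;
          if (a != b) ++m;
        }
      }
      mism(i, j) = mism(j, i) = m;
      comp(i, j) = comp(j, i) = c;
    }
  }
  return List::create(Named("mismatch") = mism, Named("comparable") = comp);
}
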
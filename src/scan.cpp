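#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window log-odds scores of an encoded sequence (1..4, NA for N).
// Windows containing NA score NA. lod is the 4 x width log-odds matrix.
// [[Rcpp::export(name = ".scan_scores")]]
NumericVector scan_scores(IntegerVector enc, NumericMatrix lod) {
  const int w = lod.ncol();
  const int n = enc.size();
  const int nw = n - w + 1;
  if (nw < 1) return NumericVector(0);
  NumericVector s(nw);
  std::vector<double> L(4 * w);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) L[4 * j + b] = lod(b, j);
  const int *e = INTEGER(enc);
  for (int i = 0; i < nw; ++i) {
    double acc = 0.0;
    bool na = false;
    for (int j = 0; j < w; ++j) {
      const int b = e[i + j];
      if (b == NA_INTEGER) { na = true; break; }
      acc += L[4 * j + b - 1];
    }
    s[i] = na ? NA_REAL : acc;
  }
  return s;
}
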
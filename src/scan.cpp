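#include <Rcpp.h>
using namespace Rcpp;

// Score every width-w window of an integer-coded sequence (1..4 = A,C,G,T,
// NA = any other IUPAC code) against a 4 x w log-odds matrix. Windows
// containing an NA code score NA and are skipped by the caller.
// [[Rcpp::export]]
NumericVector scoreWindowsC(IntegerVector codes, NumericMatrix lo) {
  const int w = lo.ncol();
  const int L = codes.size();
  const int nw = L - w + 1;
  if (nw < 1) return NumericVector(0);
  NumericVector s(nw);
  const int *cd = codes.begin();
  const double *m = lo.begin();   // column-major, 4 rows
  double *out = s.begin();
  for (int i = 0; i < nw; ++i) {
    double acc = 0.0;
    bool na = false;
    for (int j = 0; j < w; ++j) {
      const int c = cd[i + j];
      if (c == NA_INTEGER) { na = true; break; }
      acc += m[4 * j + c - 1];
    }
    out[i] = na ? NA_REAL : acc;
  }
  return s;
}

// Scan and threshold in one pass: returns 1-based window positions and
// scores of windows scoring >= thresh (windows with non-ACGT codes skip).
// [[Rcpp::export]]
List scanThresholdC(IntegerVector codes, NumericMatrix lo, double thresh) {
  const int w = lo.ncol();
  const int L = codes.size();
  const int nw = L - w + 1;
  std::vector<int> pos;
  std::vector<double> sc;
  const int *cd = codes.begin();
  const double *m = lo.begin();
  for (int i = 0; i < (nw < 0 ? 0 : nw); ++i) {
    double acc = 0.0;
    bool na = false;
    for (int j = 0; j < w; ++j) {
      const int c = cd[i + j];
      if (c == NA_INTEGER) { na = true; break; }
      acc += m[4 * j + c - 1];
    }
    if (!na && acc >= thresh) {
      pos.push_back(i + 1);
      sc.push_back(acc);
    }
  }
  return List::create(_["pos"] = wrap(pos), _["score"] = wrap(sc));
}
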
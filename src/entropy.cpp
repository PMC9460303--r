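#include <Rcpp.h>
using namespace Rcpp;

// Approximate entropy with self-matches, Chebyshev distance.
// Quadratic in the segment length, hence the C++ kernel: the sliding-window
// pipeline evaluates it thousands of times per run.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  if (N < m + 2) return NA_REAL;
  double phi[2] = {0.0, 0.0};
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int nt = N - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < nt; ++i) {
      int cnt = 0;
      for (int j = 0; j < nt; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double ad = std::abs(x[i + k] - x[j + k]);
          if (ad > d) d = ad;
          if (d > r) break;
        }
        if (d <= r) ++cnt;
      }
      acc += std::log((double)cnt / (double)nt);
    }
    phi[s] = acc / (double)nt;
  }
  return phi[0] - phi[1];
}
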
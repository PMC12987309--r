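#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Chebyshev-distance template counting for approximate and sample entropy.
// Straightforward O(N^2) pair scans; tolerance r is passed in absolute units.

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  if (N <= m + 1) stop("series too short for the requested embedding");
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    const int mm = m + s;
    const int nT = N - mm + 1;  // templates, self-matches included
    double acc = 0.0;
    for (int i = 0; i < nT; ++i) {
      int cnt = 0;
      for (int j = 0; j < nT; ++j) {
        double dmax = 0.0;
        for (int k = 0; k < mm; ++k) {
          double d = std::fabs(x[i + k] - x[j + k]);
          if (d > dmax) dmax = d;
          if (dmax > r) break;
        }
        if (dmax <= r) ++cnt;
      }
      acc += std::log((double)cnt / (double)nT);
    }
    phi[s] = acc / (double)nT;
  }
  return phi[0] - phi[1];
}

// Returns {A, B}: (m+1)- and m-length match counts over i<j pairs with
// i, j <= N-m-1 (the same N-m templates for both lengths, self-matches
// excluded).
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  if (N <= m + 1) stop("series too short for the requested embedding");
  const int nT = N - m;  // templates of length m usable for extension
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nT - 1; ++i) {
    for (int j = i + 1; j < nT; ++j) {
      double dmax = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dmax) dmax = d;
        if (dmax > r) break;
      }
      if (dmax <= r) {
        B += 1.0;
        double d1 = std::fabs(x[i + m] - x[j + m]);
        if (std::max(dmax, d1) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
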
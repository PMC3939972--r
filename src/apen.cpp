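#include <Rcpp.h>
using namespace Rcpp;

// Template match counts for approximate entropy at embedding dimensions m and
// m + 1 in a single pass over all ordered template pairs.
//
// Templates at dimension q are X(i) = [x(i), ..., x(i + q - 1)], i = 1..N-q+1,
// compared under the Chebyshev (maximum) norm; a pair matches when the
// distance is <= r.  Because the Chebyshev distance is non-decreasing in the
// embedding dimension, a pair that fails at dimension m cannot match at m + 1,
// which lets the inner loop terminate early.
//
// With exclude_self = true the pair j == i is skipped at both dimensions (the
// denominator used by the caller is unchanged).
//
// [[Rcpp::export(name = ".apen_counts")]]
List apen_counts(NumericVector x, int m, double r, bool exclude_self) {
  const int N = x.size();
  const int nm = N - m + 1;   // templates at dimension m
  const int nm1 = N - m;      // templates at dimension m + 1
  IntegerVector count_m(nm), count_m1(nm1);

  for (int i = 0; i < nm; ++i) {
    int ci = 0, ci1 = 0;
    for (int j = 0; j < nm; ++j) {
      if (exclude_self && j == i) continue;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
        if (d > r) break;
      }
      if (d <= r) {
        ++ci;
        if (i < nm1 && j < nm1) {
          double a = std::fabs(x[i + m] - x[j + m]);
          if ((a > d ? a : d) <= r) ++ci1;
        }
      }
    }
    count_m[i] = ci;
    if (i < nm1) count_m1[i] = ci1;
  }
  return List::create(_["count_m"] = count_m, _["count_m1"] = count_m1);
}

// Lean path: the ApEn value phi_m - phi_{m+1} in one call, avoiding the R
// round trip per window.  Match frequencies use denominators N - m + 1 and
// N - m; a zero count under the exclude convention returns NA (the R caller
// raises the descriptive error).
//
// [[Rcpp::export(name = ".apen_value")]]
double apen_value(NumericVector x, int m, double r, bool exclude_self) {
  const int N = x.size();
  const int nm = N - m + 1;
  const int nm1 = N - m;
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nm; ++i) {
    int ci = 0, ci1 = 0;
    for (int j = 0; j < nm; ++j) {
      if (exclude_self && j == i) continue;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
        if (d > r) break;
      }
      if (d <= r) {
        ++ci;
        if (i < nm1 && j < nm1) {
          double a = std::fabs(x[i + m] - x[j + m]);
          if ((a > d ? a : d) <= r) ++ci1;
        }
      }
    }
    if (ci == 0 || (i < nm1 && ci1 == 0)) return NA_REAL;
    phi_m += std::log((double)ci / nm);
    if (i < nm1) phi_m1 += std::log((double)ci1 / nm1);
  }
  return phi_m / nm - phi_m1 / nm1;
}
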
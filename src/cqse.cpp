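#include <Rcpp.h>

// Cross match probability between template sets of two series.
//
// Counts pairs (i, j), i = 1..N-m, j = 1..M-m, whose length-m templates
// X[i..i+m-1] and Y[j..j+m-1] lie within Chebyshev distance r of each other
// (d <= r counts: the Heaviside step is taken as 1 at zero). Note the
// denominators deliberately exclude the last template of each series so that
// the same index ranges serve both the m and the m+1 template counts.
//
// [[Rcpp::export]]
double cross_match_probability_cpp(Rcpp::NumericVector x, Rcpp::NumericVector y,
                                   int m, double r) {
  const int N = x.size(), M = y.size();
  const int ni = N - m, nj = M - m;
  if (m < 1) Rcpp::stop("`m` must be >= 1");
  if (ni < 1 || nj < 1) Rcpp::stop("series too short for template length m");
  long long count = 0;
  for (int i = 0; i < ni; ++i) {
    for (int j = 0; j < nj; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - y[j + k]);
        if (a > d) d = a;
        if (d > r) break;
      }
      if (d <= r) ++count;
    }
  }
  return static_cast<double>(count) /
         (static_cast<double>(ni) * static_cast<double>(nj));
}
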
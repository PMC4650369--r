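#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Two-sample Anderson-Darling statistic in the tie-adjusted midrank form
// (the "A2akN" variant: discrete version with continuity correction).
// Values contributing a zero denominator (degenerate strata) are skipped;
// a fully constant pooled sample yields 0.
// [[Rcpp::export]]
double ad2_stat_cpp(NumericVector x, NumericVector y) {
  const int n1 = x.size(), n2 = y.size();
  const int N = n1 + n2;
  std::vector< std::pair<double, int> > z;
  z.reserve(N);
  for (int i = 0; i < n1; ++i) z.push_back(std::make_pair(x[i], 0));
  for (int i = 0; i < n2; ++i) z.push_back(std::make_pair(y[i], 1));
  std::sort(z.begin(), z.end());

  double A = 0.0;
  double Bj = 0.0;  // pooled count strictly below the current distinct value
  double M1 = 0.0;  // sample-1 count strictly below
  bool any = false;
  int i = 0;
  while (i < N) {
    int j = i, lj = 0, l1 = 0;
    while (j < N && z[j].first == z[i].first) {
      ++lj;
      if (z[j].second == 0) ++l1;
      ++j;
    }
    const double Baj = Bj + lj / 2.0;   // midrank pooled count
    const double Ma1 = M1 + l1 / 2.0;   // midrank count, sample 1
    const double Ma2 = Baj - Ma1;       // midrank count, sample 2
    const double denom = Baj * (N - Baj) - N * lj / 4.0;
    if (denom > 0) {
      const double t1 = N * Ma1 - (double)n1 * Baj;
      const double t2 = N * Ma2 - (double)n2 * Baj;
      A += ((double)lj / N) * (t1 * t1 / n1 + t2 * t2 / n2) / denom;
      any = true;
    }
    Bj += lj;
    M1 += l1;
    i = j;
  }
  if (!any) return 0.0;
  return A * (N - 1.0) / N;
}
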
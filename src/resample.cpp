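// Inner loop of the two-sample Monte Carlo resampling test.
// Uses R's RNG (deterministic under set.seed); permutation draws a random
// relabelling of the pooled values each iteration via partial Fisher-Yates.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
double permTestCount(NumericVector pool, int n_a, double n_iter,
                     double obs_stat, bool two_sided, bool bootstrap) {
  int n = pool.size();
  int n_b = n - n_a;
  if (n_a < 1 || n_b < 1) stop("both groups must be non-empty");
  long B = (long)n_iter;
  if (B < 1) stop("n_iterations must be >= 1");

  std::vector<double> v(pool.begin(), pool.end());
  double S = 0.0;
  for (int i = 0; i < n; ++i) S += v[i];

  // tie tolerance so exact rearrangements of the observed split count as >=
  double eps = 1e-9 * std::max(1.0, std::fabs(obs_stat));
  double cnt = 0.0;

  for (long it = 0; it < B; ++it) {
    double diff;
    if (!bootstrap) {
      double sA = 0.0;
      for (int i = 0; i < n_a; ++i) {
        int j = i + (int)std::floor(unif_rand() * (double)(n - i));
        if (j >= n) j = n - 1;
        double tmp = v[i]; v[i] = v[j]; v[j] = tmp;
        sA += v[i];
      }
      diff = sA / n_a - (S - sA) / n_b;
    } else {
      double sA = 0.0, sB = 0.0;
      for (int i = 0; i < n_a; ++i) {
        int j = (int)std::floor(unif_rand() * (double)n);
        if (j >= n) j = n - 1;
        sA += v[j];
      }
      for (int i = 0; i < n_b; ++i) {
        int j = (int)std::floor(unif_rand() * (double)n);
        if (j >= n) j = n - 1;
        sB += v[j];
      }
      diff = sA / n_a - sB / n_b;
    }
    double stat = two_sided ? std::fabs(diff) : diff;
    if (stat >= obs_stat - eps) cnt += 1.0;
  }
  return cnt;
}
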
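#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Circular binary segmentation arc scan.
//
// For a probe-ordered signal x of length n, considers every circular arc
// (i, j] with min_width <= j - i <= n - min_width and computes the
// two-sample t-like statistic
//   T = (mean_in - mean_out) / (s * sqrt(1/n_in + 1/n_out))
// with the pooled residual s from the two groups.  Returns the arc
// maximizing |T|; ties are broken by the smallest (i, j) in scan order
// (i ascending, then j ascending).  A perfect split of a noiseless step
// has s = 0 and is assigned a large sentinel statistic.

static const double T_PERFECT = 1e18;

static double arc_stat(double sum_in, double q_total, double total,
                       int n_in, int n_out) {
  double mean_in = sum_in / n_in;
  double mean_out = (total - sum_in) / n_out;
  double diff = mean_in - mean_out;
  double ss = q_total - n_in * mean_in * mean_in - n_out * mean_out * mean_out;
  if (ss < 0) ss = 0;
  int n = n_in + n_out;
  double s2 = (n > 2) ? ss / (n - 2) : 0.0;
  double denom = std::sqrt(s2 * (1.0 / n_in + 1.0 / n_out));
  if (denom < 1e-14) {
    return (std::fabs(diff) > 1e-14) ? ((diff > 0) ? T_PERFECT : -T_PERFECT)
                                     : 0.0;
  }
  return diff / denom;
}

struct ScanResult {
  int i, j;
  double t;
};

static ScanResult scan(const std::vector<double>& x, int min_width) {
  int n = (int)x.size();
  ScanResult best;
  best.i = -1; best.j = -1; best.t = 0.0;
  if (n < 2 * min_width) return best;
  std::vector<double> S(n + 1, 0.0), Q(n + 1, 0.0);
  for (int k = 0; k < n; ++k) {
    S[k + 1] = S[k] + x[k];
    Q[k + 1] = Q[k] + x[k] * x[k];
  }
  double total = S[n], q_total = Q[n];
  double best_abs = -1.0;
  int wmax = n - min_width;
  for (int i = 0; i <= n - min_width; ++i) {
    int jhi = i + wmax; if (jhi > n) jhi = n;
    for (int j = i + min_width; j <= jhi; ++j) {
      double t = arc_stat(S[j] - S[i], q_total, total, j - i, n - (j - i));
      double a = std::fabs(t);
      if (a > best_abs) {
        best_abs = a;
        best.i = i; best.j = j; best.t = t;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cbs_scan_arcs(NumericVector x, int min_width) {
  std::vector<double> v(x.begin(), x.end());
  ScanResult r = scan(v, min_width);
  return List::create(_["i"] = r.i, _["j"] = r.j, _["t"] = r.t);
}

// Permutation exceedance count for the observed max |T|.
//
// Shuffles x with R's RNG (so results follow set.seed), rescans, and counts
// permutations whose max |T| reaches t_obs.  Stops early once the count
// reaches max_exceed, at which point the split can no longer be significant.
// Returns c(count, permutations_done).

// [[Rcpp::export]]
IntegerVector cbs_perm_count(NumericVector x, int min_width, double t_obs,
                             int nperm, int max_exceed) {
  int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  int count = 0, done = 0;
  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates with R uniforms
    for (int k = n - 1; k > 0; --k) {
      int m = (int)(unif_rand() * (k + 1));
      if (m > k) m = k;
      std::swap(v[k], v[m]);
    }
    ScanResult r = scan(v, min_width);
    ++done;
    if (std::fabs(r.t) >= t_obs) {
      if (++count >= max_exceed) break;
    }
  }
  return IntegerVector::create(count, done);
}
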
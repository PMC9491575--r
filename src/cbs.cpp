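#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation kernel: maximal t-like arc statistic and its
// permutation reference distribution. The arc (i, j] (0-based i, probes
// i+1..j in 1-based terms) is tested against the complement; arc and
// complement must both contain at least min_width probes, and the edge
// pieces left over by a split are kept at min_width or merged away by the
// loop bounds (i is 0 or >= min_width; j is n or <= n - min_width).

static void max_arc_stat(const std::vector<double>& x, int min_width,
                         double& best, int& bi, int& bj) {
  int n = (int)x.size();
  std::vector<double> S(n + 1, 0.0);
  double ss = 0.0;
  for (int t = 0; t < n; ++t) {
    S[t + 1] = S[t] + x[t];
    ss += x[t] * x[t];
  }
  double total = S[n];
  double var_all = (ss - total * total / n) / std::max(1, n - 1);
  best = 0.0; bi = 0; bj = 0;
  if (var_all <= 0.0) return;  // constant signal: no split
  double sd = std::sqrt(var_all);
  for (int i = 0; i <= n - min_width; ++i) {
    if (i != 0 && i < min_width) continue;       // left edge piece too short
    int jmax = n - min_width;
    for (int j = i + min_width; j <= n; ++j) {
      if (j != n && j > jmax) continue;          // right edge piece too short
      int k = j - i;
      if (n - k < min_width) continue;           // complement too short
      double m1 = (S[j] - S[i]) / k;
      double m0 = (total - S[j] + S[i]) / (n - k);
      double stat = std::fabs(m1 - m0) /
        (sd * std::sqrt(1.0 / k + 1.0 / (n - k)));
      if (stat > best) { best = stat; bi = i; bj = j; }
    }
  }
}

// [[Rcpp::export]]
NumericVector cbs_scan(NumericVector x, int min_width) {
  std::vector<double> v(x.begin(), x.end());
  double best; int bi, bj;
  max_arc_stat(v, min_width, best, bi, bj);
  return NumericVector::create(best, (double)bi, (double)bj);
}

// [[Rcpp::export]]
int cbs_perm_count(NumericVector x, int min_width, int n_perm, double obs) {
  std::vector<double> v(x.begin(), x.end());
  int n = (int)v.size();
  int count = 0;
  RNGScope scope;  // use R's RNG so results follow set.seed()
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle driven by R's uniform generator
    for (int t = n - 1; t > 0; --t) {
      int u = (int)std::floor(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(v[t], v[u]);
    }
    double best; int bi, bj;
    max_arc_stat(v, min_width, best, bi, bj);
    if (best >= obs - 1e-12) ++count;
  }
  return count;
}
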
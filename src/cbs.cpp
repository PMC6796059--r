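#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation split scan.
//
// For a vector x[0..n-1] an arc is a pair (i, j), 0 <= i < j <= n, covering
// bins i..j-1.  The split statistic is the two-sample t-like statistic
// comparing the arc mean against the complement mean, with the variance
// estimated once from the whole piece (so it is constant across arcs and
// invariant under permutation):
//
//   T(i,j) = |mean(arc) - mean(rest)| / (s * sqrt(1/k + 1/(n-k)))
//
// Only arcs whose acceptance leaves every resulting linear piece with at
// least min_bins bins are scanned: arc length >= min_bins, complement
// length >= min_bins, and each non-empty flank (left of i, right of j)
// >= min_bins.  Ties are broken by the earliest (smallest i, then smallest
// j, hence shortest) arc because the scan only replaces on strict
// improvement.

struct ArcScan {
  double stat;
  int i, j;  // arc covers bins i..j-1; stat < 0 when no admissible arc
};

static ArcScan max_arc_stat(const std::vector<double>& x, int min_bins) {
  const int n = static_cast<int>(x.size());
  ArcScan best = {-1.0, -1, -1};
  if (n < 2 * min_bins) return best;

  std::vector<double> S(n + 1, 0.0);
  for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
  const double total = S[n];

  for (int i = 0; i <= n - min_bins; ++i) {
    if (i != 0 && i < min_bins) continue;  // left flank too short
    for (int j = i + min_bins; j <= n; ++j) {
      const int rf = n - j;                // right flank
      if (rf != 0 && rf < min_bins) continue;
      const int k = j - i;
      const int m = n - k;                 // complement length
      if (m < min_bins) continue;          // also skips the full-span arc
      const double arc_sum = S[j] - S[i];
      const double diff = arc_sum / k - (total - arc_sum) / m;
      const double z = std::fabs(diff) / std::sqrt(1.0 / k + 1.0 / m);
      if (z > best.stat) {
        best.stat = z;
        best.i = i;
        best.j = j;
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".cbs_split_cpp")]]
List cbs_split_cpp(NumericVector x, int min_bins, double alpha, int n_perm) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());

  // piece variance; a (near-)constant piece never splits
  double mean = 0.0;
  for (double e : v) mean += e;
  mean /= std::max(n, 1);
  double ss = 0.0;
  for (double e : v) ss += (e - mean) * (e - mean);
  const double sd = n > 1 ? std::sqrt(ss / (n - 1)) : 0.0;

  ArcScan obs = max_arc_stat(v, min_bins);
  if (obs.i < 0 || sd < 1e-12) {
    return List::create(_["split"] = false, _["i"] = NA_INTEGER,
                        _["j"] = NA_INTEGER, _["stat"] = NA_REAL,
                        _["p_value"] = NA_REAL);
  }
  const double obs_stat = obs.stat / sd;

  // permutation reference for the max statistic, with early stopping once
  // the exceedance count guarantees p >= alpha; p = (1 + count) / (1 + B)
  const int cnt_max =
      static_cast<int>(std::floor(alpha * (1.0 + n_perm))) - 1;
  int count = 0, done = 0;
  if (cnt_max < 0) {
    count = cnt_max + 1;  // alpha so small no permutation budget can reject
  } else {
    RNGScope scope;
    std::vector<double> perm(v);
    for (int b = 0; b < n_perm; ++b) {
      // Fisher-Yates using R's RNG so set.seed() governs the result
      for (int t = n - 1; t > 0; --t) {
        int u = static_cast<int>(unif_rand() * (t + 1));
        if (u > t) u = t;
        std::swap(perm[t], perm[u]);
      }
      ArcScan ps = max_arc_stat(perm, min_bins);
      ++done;
      if (ps.stat / sd >= obs_stat) {
        ++count;
        if (count > cnt_max) break;  // cannot reach p < alpha any more
      }
    }
  }
  const double p = (1.0 + count) / (1.0 + std::max(done, 1));
  const bool split = count <= cnt_max;
  return List::create(_["split"] = split, _["i"] = obs.i, _["j"] = obs.j,
                      _["stat"] = obs_stat, _["p_value"] = p,
                      _["perms_done"] = done);
}
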
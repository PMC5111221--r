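#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation scan statistic.
//
// For markers x_1..x_m the candidate change is an arc (i, j] of the
// circularised sequence; linearly that is every contiguous window whose
// complement is the remainder of the chromosome. The statistic is the
// two-sample t between window and complement with pooled variance. The
// permutation null shuffles marker labels.

struct ScanResult {
  double t;
  int i; // 0-based split before window
  int j; // 0-based split after window (window = [i, j))
};

static ScanResult scan_max_t(const std::vector<double>& x, int min_width) {
  const int m = (int)x.size();
  ScanResult best = {0.0, 0, m};
  if (m < 2 * min_width) return best;

  std::vector<double> S(m + 1, 0.0), Q(m + 1, 0.0);
  for (int k = 0; k < m; ++k) {
    S[k + 1] = S[k] + x[k];
    Q[k + 1] = Q[k] + x[k] * x[k];
  }
  const double T = S[m], QT = Q[m];
  const double dfinv = 1.0 / std::max(m - 2, 1);

  double best_abs = -1.0;
  for (int n = min_width; n <= m - min_width; ++n) {
    const double inv_n = 1.0 / n, inv_c = 1.0 / (m - n);
    const double se_geom = inv_n + inv_c;
    for (int i = 0; i + n <= m; ++i) {
      const double W = S[i + n] - S[i];
      const double QW = Q[i + n] - Q[i];
      double ss_in = QW - W * W * inv_n;
      double ss_out = (QT - QW) - (T - W) * (T - W) * inv_c;
      double s2 = (ss_in + ss_out) * dfinv;
      if (s2 < 1e-24) s2 = 1e-24;
      const double t = (W * inv_n - (T - W) * inv_c) / std::sqrt(s2 * se_geom);
      const double a = std::fabs(t);
      if (a > best_abs) {
        best_abs = a;
        best.t = t;
        best.i = i;
        best.j = i + n;
      }
    }
  }
  if (best_abs < 0) best_abs = 0.0;
  best.t = best_abs * ((best.t < 0) ? -1.0 : 1.0);
  return best;
}

// [[Rcpp::export(name = ".cbs_scan")]]
List cbs_scan(NumericVector x, int min_width) {
  std::vector<double> v(x.begin(), x.end());
  ScanResult r = scan_max_t(v, min_width);
  return List::create(_["t"] = r.t, _["i"] = r.i, _["j"] = r.j);
}

// Permutation p-value for the max |t| statistic with sequential early
// stopping: stop-reject once the exceedance count already forces
// p >= alpha whatever the remaining permutations do; stop-accept once the
// running estimate is clearly below alpha (p-hat < alpha / 2 after at
// least 300 permutations). Uses R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".cbs_test")]]
List cbs_test(NumericVector x, int min_width, int n_perm, double alpha) {
  std::vector<double> v(x.begin(), x.end());
  const int m = (int)v.size();
  ScanResult obs = scan_max_t(v, min_width);
  const double t_obs = std::fabs(obs.t);

  RNGScope scope;
  int k = 0, done = 0;
  const double reject_k = alpha * (n_perm + 1); // k + 1 > this => p >= alpha
  std::vector<double> perm(v);
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle
    for (int u = m - 1; u > 0; --u) {
      int w = (int)std::floor(unif_rand() * (u + 1));
      if (w > u) w = u;
      std::swap(perm[u], perm[w]);
    }
    ScanResult pr = scan_max_t(perm, min_width);
    if (std::fabs(pr.t) >= t_obs - 1e-12) ++k;
    ++done;
    if (k + 1 > reject_k) break;
    if (done >= 300 && (double)(k + 1) / (done + 1) < alpha / 2.0) break;
  }
  const double p = (double)(k + 1) / (done + 1);
  return List::create(_["t"] = obs.t, _["i"] = obs.i, _["j"] = obs.j,
                      _["p"] = p, _["n_perm_used"] = done);
}
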
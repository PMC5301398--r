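#include <Rcpp.h>
using namespace Rcpp;

// Arc-scan kernel for the binary-segmentation caller: maximal
// standardized contrast of a sub-interval (arc) against the rest of
// the segment, over all start positions and a grid of widths.
// Prefix sums are recomputed per call; s is the robust noise sd.

static double scan_max(const std::vector<double> &S, int n,
                       const IntegerVector &widths, double s,
                       int *best_i, int *best_w) {
  double best = -1.0;
  double total = S[n];
  for (int wi = 0; wi < widths.size(); ++wi) {
    int w = widths[wi];
    if (w < 1 || w >= n) continue;
    double denom = s * std::sqrt(1.0 / w + 1.0 / (n - w));
    for (int i = 0; i + w <= n; ++i) {
      double sum_in = S[i + w] - S[i];
      double t = std::fabs(sum_in / w - (total - sum_in) / (n - w)) / denom;
      if (t > best) {
        best = t;
        if (best_i) *best_i = i + 1;  // 1-based left edge
        if (best_w) *best_w = w;
      }
    }
  }
  return best;
}

static void prefix_sums(const std::vector<double> &y,
                        std::vector<double> &S) {
  S[0] = 0.0;
  for (size_t k = 0; k < y.size(); ++k) S[k + 1] = S[k] + y[k];
}

//' Arc-statistic permutation test of one segment (internal)
//'
//' Computes the maximal arc statistic of `y` over the width grid and
//' compares it with the same scan on random shuffles of `y` (R's RNG;
//' reproducible under set.seed).  Stops early once more than
//' `max_reject` permutation maxima reach the observed maximum.
//'
//' @param y numeric segment values.
//' @param widths integer width grid.
//' @param s robust noise sd.
//' @param n_perm number of permutations.
//' @param max_reject early-exit threshold on the exceedance count.
//' @return list with the observed statistic `t`, arc start `i` (1-based),
//'   width `w`, and exceedance count `count`.
//' @keywords internal
// [[Rcpp::export(name = ".cbs_perm_test")]]
List cbs_perm_test(NumericVector y, IntegerVector widths, double s,
                   int n_perm, int max_reject) {
  int n = y.size();
  std::vector<double> yy(y.begin(), y.end());
  std::vector<double> S(n + 1);
  prefix_sums(yy, S);
  int obs_i = NA_INTEGER, obs_w = NA_INTEGER;
  double obs = scan_max(S, n, widths, s, &obs_i, &obs_w);
  int cnt = 0;
  if (R_finite(obs) && obs >= 0) {
    RNGScope scope;  // draw from R's RNG stream
    std::vector<double> yp(yy);
    for (int p = 0; p < n_perm; ++p) {
      for (int k = n - 1; k > 0; --k) {  // Fisher-Yates shuffle
        int j = (int)(unif_rand() * (k + 1));
        if (j > k) j = k;
        std::swap(yp[k], yp[j]);
      }
      prefix_sums(yp, S);
      double t = scan_max(S, n, widths, s, nullptr, nullptr);
      if (t >= obs) {
        ++cnt;
        if (cnt > max_reject) break;
      }
    }
  }
  return List::create(_["t"] = obs, _["i"] = obs_i, _["w"] = obs_w,
                      _["count"] = cnt);
}
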
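#include <Rcpp.h>
using namespace Rcpp;

// Weighted pool-adjacent-violators: isotonic (non-decreasing) means with
// group sizes as weights. Returns the amalgamated means.
static void pava(const double* y, const double* w, int g, double* out) {
  std::vector<double> level(g), weight(g);
  std::vector<int> count(g);
  int k = 0;
  for (int i = 0; i < g; ++i) {
    level[k] = y[i];
    weight[k] = w[i];
    count[k] = 1;
    while (k > 0 && level[k - 1] > level[k]) {
      double tw = weight[k - 1] + weight[k];
      level[k - 1] = (level[k - 1] * weight[k - 1] + level[k] * weight[k]) / tw;
      weight[k - 1] = tw;
      count[k - 1] += count[k];
      --k;
    }
    ++k;
  }
  int pos = 0;
  for (int b = 0; b < k; ++b)
    for (int j = 0; j < count[b]; ++j) out[pos++] = level[b];
}

// [[Rcpp::export]]
NumericVector cpp_pava(NumericVector y, NumericVector w) {
  int g = y.size();
  NumericVector out(g);
  pava(REAL(y), REAL(w), g, REAL(out));
  return out;
}

// Williams-type trend statistic for one probe given group means already
// amalgamated: (isotonic mean of top group - raw control mean) / SE.
// Degenerate pooled variance: statistic is +Inf when the difference is
// nonzero (any permuted tie then counts as an exceedance), 0 otherwise.
static double williams_t(const double* means, const double* w, int g,
                         double s2, double se_scale, double* scratch) {
  pava(means, w, g, scratch);
  double diff = scratch[g - 1] - means[0];
  if (s2 <= 0.0) return diff > 1e-12 ? R_PosInf : 0.0;
  return diff / std::sqrt(s2 * se_scale);
}

// Permutation Williams trend test over a probe-by-sample matrix.
// groups: 0-based group index per sample, 0 = control, ordered by
// concentration. perms: B x n matrix of 1-based permuted sample indices
// (as produced by R's sample.int).
// Returns observed statistics for both directions and permutation
// exceedance counts.
// [[Rcpp::export]]
List cpp_williams(NumericMatrix values, IntegerVector groups,
                  IntegerMatrix perms) {
  const int p = values.nrow(), n = values.ncol();
  int g = 0;
  for (int j = 0; j < n; ++j) g = std::max(g, groups[j] + 1);
  std::vector<double> w(g, 0.0);
  for (int j = 0; j < n; ++j) w[groups[j]] += 1.0;
  const int B = perms.nrow();
  const double se_scale = 1.0 / w[0] + 1.0 / w[g - 1];

  NumericVector t_up(p), t_down(p);
  IntegerVector ge_up(p, 0), ge_down(p, 0);

  std::vector<double> means(g), sumsq(g), scratch(g), neg(g);
  std::vector<int> gidx(n);

  for (int b = -1; b < B; ++b) {
    if (b < 0) {
      for (int j = 0; j < n; ++j) gidx[j] = groups[j];
    } else {
      for (int j = 0; j < n; ++j) gidx[j] = groups[perms(b, j) - 1];
    }
    for (int i = 0; i < p; ++i) {
      std::fill(means.begin(), means.end(), 0.0);
      std::fill(sumsq.begin(), sumsq.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        double v = values(i, j);
        means[gidx[j]] += v;
        sumsq[gidx[j]] += v * v;
      }
      double rss = 0.0;
      for (int k = 0; k < g; ++k) {
        means[k] /= w[k];
        rss += sumsq[k] - w[k] * means[k] * means[k];
      }
      double s2 = rss / (n - g);
      if (s2 < 0.0) s2 = 0.0; // numerical guard
      double tu = williams_t(means.data(), w.data(), g, s2, se_scale,
                             scratch.data());
      for (int k = 0; k < g; ++k) neg[k] = -means[k];
      double td = williams_t(neg.data(), w.data(), g, s2, se_scale,
                             scratch.data());
      if (b < 0) {
        t_up[i] = tu;
        t_down[i] = td;
      } else {
        if (tu >= t_up[i]) ++ge_up[i];
        if (td >= t_down[i]) ++ge_down[i];
      }
    }
  }
  return List::create(_["t_up"] = t_up, _["t_down"] = t_down,
                      _["ge_up"] = ge_up, _["ge_down"] = ge_down,
                      _["B"] = B);
}
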
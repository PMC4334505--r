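#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Exact least-squares piecewise-constant segmentation by dynamic programming.
// For every S = 1..maxSegments the boundary placement minimizing the residual
// sum of squares of the S-segment constant fit is found (not a heuristic).
// Returns RSS(S) and the changepoint sets; BIC model selection happens in R.

// [[Rcpp::export(name = ".segment_dp_cpp")]]
List segment_dp_cpp(NumericVector x, int maxSegments) {
  int n = x.size();
  if (maxSegments < 1) stop("maxSegments must be >= 1");
  if (maxSegments > n) maxSegments = n;

  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  // cost of fitting one constant over x[i..j] (0-based inclusive)
  auto cost = [&](int i, int j) {
    double s = cs[j + 1] - cs[i];
    double s2 = cs2[j + 1] - cs2[i];
    int m = j - i + 1;
    double c = s2 - s * s / m;
    return c < 0 ? 0.0 : c;
  };

  const double INF = 1e300;
  // D[s][j]: min RSS for first j points in s segments
  std::vector<std::vector<double> > D(maxSegments + 1,
                                      std::vector<double>(n + 1, INF));
  std::vector<std::vector<int> > B(maxSegments + 1,
                                   std::vector<int>(n + 1, -1));
  D[0][0] = 0.0;
  for (int s = 1; s <= maxSegments; ++s) {
    for (int j = s; j <= n; ++j) {
      double best = INF;
      int bestk = -1;
      for (int k = s - 1; k <= j - 1; ++k) {
        if (D[s - 1][k] >= INF) continue;
        double v = D[s - 1][k] + cost(k, j - 1);
        if (v < best) { best = v; bestk = k; }
      }
      D[s][j] = best;
      B[s][j] = bestk;
    }
  }

  NumericVector rss(maxSegments);
  List bounds(maxSegments);
  for (int s = 1; s <= maxSegments; ++s) {
    rss[s - 1] = D[s][n];
    // recover segment start indices (1-based) for the S-segment solution
    std::vector<int> starts;
    int j = n, t = s;
    while (t >= 1) {
      int k = B[t][j];
      starts.push_back(k + 1);  // 1-based start of segment t
      j = k;
      --t;
    }
    IntegerVector st(starts.rbegin(), starts.rend());
    bounds[s - 1] = st;
  }
  return List::create(_["rss"] = rss, _["starts"] = bounds);
}
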
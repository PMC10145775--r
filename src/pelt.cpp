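#include <Rcpp.h>
using namespace Rcpp;

// Exact penalized mean-shift change-point detection (PELT).
//
// Minimizes sum of within-segment squared deviations from the segment mean
// plus beta * (number of breakpoints), over all segmentations whose segments
// have length >= min_size. Pruning is exact for this additive cost.
// Breakpoints are 0-based segment starts, strictly inside (0, n); ties are
// broken toward the smallest admissible previous breakpoint (earliest, hence
// fewest, breaks).
//
// [[Rcpp::export]]
List pelt_core(NumericMatrix y, double beta, int min_size) {
  const int n = y.nrow(), d = y.ncol();
  // cumulative sums: S1[(t)*d + j] = sum of y[0..t-1, j]; s2[t] = sum of ||y_i||^2
  std::vector<double> S1((size_t)(n + 1) * d, 0.0), s2(n + 1, 0.0);
  for (int t = 0; t < n; ++t) {
    double q = 0.0;
    for (int j = 0; j < d; ++j) {
      double v = y(t, j);
      S1[(size_t)(t + 1) * d + j] = S1[(size_t)t * d + j] + v;
      q += v * v;
    }
    s2[t + 1] = s2[t] + q;
  }
  auto seg_cost = [&](int a, int b) {
    double csq = 0.0;
    const double *pa = &S1[(size_t)a * d], *pb = &S1[(size_t)b * d];
    for (int j = 0; j < d; ++j) {
      double diff = pb[j] - pa[j];
      csq += diff * diff;
    }
    return (s2[b] - s2[a]) - csq / (b - a);
  };

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> F(n + 1, INF);
  std::vector<int> prev(n + 1, -1);
  F[0] = -beta;
  std::vector<int> cand;
  std::vector<int> marked; // step at which the prune condition first held
  cand.reserve(256);
  marked.reserve(256);
  cand.push_back(0);
  marked.push_back(-1);
  for (int t = min_size; t <= n; ++t) {
    if (t - min_size >= min_size) {
      cand.push_back(t - min_size);
      marked.push_back(-1);
    }
    double best = INF;
    int arg = -1;
    std::vector<double> vals(cand.size());
    for (size_t i = 0; i < cand.size(); ++i) {
      int s = cand[i];
      double v = F[s] + seg_cost(s, t);
      vals[i] = v;
      if (v + beta < best) {
        best = v + beta;
        arg = s;
      }
    }
    F[t] = best;
    prev[t] = arg;
    // Candidate s is dominated for all t' >= tau + min_size once
    // F[s] + cost(s, tau) > F[tau] held at some step tau (the via-tau path
    // is only feasible from tau + min_size on), so removal is deferred.
    double tol = 1e-12 * std::max(1.0, std::fabs(F[t]));
    size_t k = 0;
    for (size_t i = 0; i < cand.size(); ++i) {
      if (marked[i] < 0 && vals[i] > F[t] + tol) marked[i] = t;
      if (marked[i] < 0 || marked[i] > t - min_size) {
        cand[k] = cand[i];
        marked[k] = marked[i];
        ++k;
      }
    }
    cand.resize(k);
    marked.resize(k);
  }

  std::vector<int> bps;
  for (int t = prev[n]; t > 0; t = prev[t]) bps.push_back(t);
  std::reverse(bps.begin(), bps.end());
  return List::create(
    _["breakpoints"] = IntegerVector(bps.begin(), bps.end()),
    _["risk"] = F[n]);
}
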
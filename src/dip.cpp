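// Dip statistic of unimodality: the sup-norm distance between the empirical
// cdf and the nearest unimodal (convex-then-concave) cdf, computed by
// fitting greatest-convex-minorant / least-concave-majorant envelopes on
// either side of candidate mode locations and taking the smallest worst-case
// envelope gap. The p-value (in R) is Monte Carlo against the uniform null,
// the least favorable unimodal distribution.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double cross(double ax, double ay, double bx, double by,
                           double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// max gap F_i - hull(x_i) for the greatest convex minorant of points 0..k
static double gcm_gap(const std::vector<double>& x,
                      const std::vector<double>& F, int k) {
  int m = 0;
  std::vector<int> h(k + 1);
  for (int i = 0; i <= k; ++i) {
    while (m >= 2 && cross(x[h[m - 2]], F[h[m - 2]], x[h[m - 1]], F[h[m - 1]],
                           x[i], F[i]) <= 0.0)
      --m;
    h[m++] = i;
  }
  // evaluate hull at every x_i and track the largest gap above it
  double gap = 0.0;
  int seg = 0;
  for (int i = 0; i <= k; ++i) {
    while (seg < m - 2 && x[h[seg + 1]] < x[i]) ++seg;
    double x0 = x[h[seg]], y0 = F[h[seg]];
    double x1 = x[h[seg + 1 > m - 1 ? m - 1 : seg + 1]];
    double y1 = F[h[seg + 1 > m - 1 ? m - 1 : seg + 1]];
    double hv = (x1 > x0) ? y0 + (y1 - y0) * (x[i] - x0) / (x1 - x0)
                          : std::min(y0, y1);
    double d = F[i] - hv;
    if (d > gap) gap = d;
  }
  return gap;
}

// max gap hull(x_i) - F_i for the least concave majorant of points k..n-1
static double lcm_gap(const std::vector<double>& x,
                      const std::vector<double>& F, int k, int n) {
  int m = 0;
  std::vector<int> h(n - k);
  for (int i = k; i < n; ++i) {
    while (m >= 2 && cross(x[h[m - 2]], F[h[m - 2]], x[h[m - 1]], F[h[m - 1]],
                           x[i], F[i]) >= 0.0)
      --m;
    h[m++] = i;
  }
  double gap = 0.0;
  int seg = 0;
  for (int i = k; i < n; ++i) {
    while (seg < m - 2 && x[h[seg + 1]] < x[i]) ++seg;
    double x0 = x[h[seg]], y0 = F[h[seg]];
    double x1 = x[h[seg + 1 > m - 1 ? m - 1 : seg + 1]];
    double y1 = F[h[seg + 1 > m - 1 ? m - 1 : seg + 1]];
    double hv = (x1 > x0) ? y0 + (y1 - y0) * (x[i] - x0) / (x1 - x0)
                          : std::max(y0, y1);
    double d = hv - F[i];
    if (d > gap) gap = d;
  }
  return gap;
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector xsorted, int max_modes = 201) {
  int n = xsorted.size();
  if (n < 4) return 0.0;
  std::vector<double> x(xsorted.begin(), xsorted.end());
  std::vector<double> F(n);
  for (int i = 0; i < n; ++i) F[i] = (i + 0.5) / n;

  // candidate mode indices: an even spread over the order statistics
  std::vector<int> modes;
  if (n <= max_modes) {
    for (int i = 0; i < n; ++i) modes.push_back(i);
  } else {
    for (int j = 0; j < max_modes; ++j)
      modes.push_back((int)std::floor(j * (n - 1.0) / (max_modes - 1.0)));
  }

  double best = 1.0;
  for (size_t j = 0; j < modes.size(); ++j) {
    int k = modes[j];
    double gl = gcm_gap(x, F, k);
    double gr = lcm_gap(x, F, k, n);
    double t = std::max(gl, gr) / 2.0;
    if (t < best) best = t;
  }
  // resolution floor of the empirical cdf
  double floor_ = 0.5 / n;
  return best > floor_ ? best : floor_;
}
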
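#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 2D worm-like chain discretized as n_seg segments of length ls.
// Successive segment directions differ by a Gaussian deflection with
// sd = sigma = sqrt(ls / lp); this gives <cos theta(s)> = exp(-s / (2 lp))
// for a surface-equilibrated (2D) chain.  All functions draw from R's RNG
// so set.seed() on the R side makes every result reproducible.

static inline double walk_end(int n_seg, double sigma, double theta0,
                              double &ex, double &ey) {
  double th = theta0, cx = 0.0, cy = 0.0;
  for (int i = 0; i < n_seg; ++i) {
    if (i > 0) th += sigma * norm_rand();
    cx += std::cos(th);
    cy += std::sin(th);
  }
  ex = cx;
  ey = cy;
  return std::sqrt(cx * cx + cy * cy);
}

// [[Rcpp::export]]
NumericVector cpp_wlc_end_to_end(int n_chains, int n_seg, double ls,
                                 double sigma) {
  NumericVector out(n_chains);
  double ex, ey;
  for (int c = 0; c < n_chains; ++c) {
    out[c] = ls * walk_end(n_seg, sigma, 0.0, ex, ey);
  }
  return out;
}

// Full trace of a single chain: (n_seg + 1) x 2 matrix of vertices,
// first vertex at the origin, first segment along direction theta0.
// [[Rcpp::export]]
NumericMatrix cpp_wlc_chain(int n_seg, double ls, double sigma,
                            double theta0) {
  NumericMatrix out(n_seg + 1, 2);
  double th = theta0, cx = 0.0, cy = 0.0;
  out(0, 0) = 0.0;
  out(0, 1) = 0.0;
  for (int i = 0; i < n_seg; ++i) {
    if (i > 0) th += sigma * norm_rand();
    cx += ls * std::cos(th);
    cy += ls * std::sin(th);
    out(i + 1, 0) = cx;
    out(i + 1, 1) = cy;
  }
  return out;
}

static void store_trace(const std::vector<double> &x,
                        const std::vector<double> &y, NumericMatrix &m) {
  int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    m(i, 0) = x[i];
    m(i, 1) = y[i];
  }
}

static double walk_trace(int n_seg, double ls, double sigma, double theta0,
                         std::vector<double> &x, std::vector<double> &y) {
  double th = theta0, cx = 0.0, cy = 0.0;
  x[0] = 0.0;
  y[0] = 0.0;
  for (int i = 0; i < n_seg; ++i) {
    if (i > 0) th += sigma * norm_rand();
    cx += ls * std::cos(th);
    cy += ls * std::sin(th);
    x[i + 1] = cx;
    y[i + 1] = cy;
  }
  return std::sqrt(cx * cx + cy * cy);
}

// Rejection-sample a pair of arms anchored at the origin (the hinge), each
// with a uniformly random initial direction, conditional on
//   g1 in (g1_lo, g1_hi), g2 in (g2_lo, g2_hi), hh in (hh_lo, hh_hi)
// where g1, g2 are the arm end-to-end (head-hinge) distances and hh the
// distance between the two arm endpoints (head-head).  The per-arm
// constraints are rejected arm by arm; on a failed joint head-head test both
// arms are discarded, so accepted pairs follow the exact conditional WLC
// ensemble.  `tries` counts every chain simulated.
// [[Rcpp::export]]
List cpp_sample_dimer_arms(int n_seg, double ls, double sigma,
                           double g1_lo, double g1_hi,
                           double g2_lo, double g2_hi,
                           double hh_lo, double hh_hi,
                           int max_tries) {
  std::vector<double> x1(n_seg + 1), y1(n_seg + 1);
  std::vector<double> x2(n_seg + 1), y2(n_seg + 1);
  int tries = 0;
  const double TWOPI = 2.0 * M_PI;
  while (tries < max_tries) {
    double g1 = -1.0, g2 = -1.0;
    while (tries < max_tries) {
      ++tries;
      g1 = walk_trace(n_seg, ls, sigma, TWOPI * unif_rand(), x1, y1);
      if (g1 > g1_lo && g1 < g1_hi) break;
      g1 = -1.0;
    }
    if (g1 < 0.0) break;
    while (tries < max_tries) {
      ++tries;
      g2 = walk_trace(n_seg, ls, sigma, TWOPI * unif_rand(), x2, y2);
      if (g2 > g2_lo && g2 < g2_hi) break;
      g2 = -1.0;
    }
    if (g2 < 0.0) break;
    double dx = x1[n_seg] - x2[n_seg];
    double dy = y1[n_seg] - y2[n_seg];
    double hh = std::sqrt(dx * dx + dy * dy);
    if (hh > hh_lo && hh < hh_hi) {
      NumericMatrix m1(n_seg + 1, 2), m2(n_seg + 1, 2);
      store_trace(x1, y1, m1);
      store_trace(x2, y2, m2);
      return List::create(_["success"] = true, _["arm1"] = m1,
                          _["arm2"] = m2, _["g1"] = g1, _["g2"] = g2,
                          _["hh"] = hh, _["tries"] = tries);
    }
  }
  return List::create(_["success"] = false, _["tries"] = tries);
}
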
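// Frame-level template matching scores.
//
// For every (trial, frame) and every template in a bank, accumulates the
// Gaussian log-likelihood of the observed element positions (position module:
// distance from each element to the nearest point of the template's segment
// set) and of the observed element orientations (orientation module: folded
// circular difference between the element orientation and the orientation of
// the positionally nearest template segment). Matching variances are the
// template spread convolved with sensory noise, supplied already combined.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double pt_seg_dist2(double px, double py,
                                  double x0, double y0, double x1, double y1) {
  double vx = x1 - x0, vy = y1 - y0;
  double wx = px - x0, wy = py - y0;
  double l2 = vx * vx + vy * vy;
  double t = (wx * vx + wy * vy) / l2;
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  double dx = wx - t * vx, dy = wy - t * vy;
  return dx * dx + dy * dy;
}

static inline double fold_ori(double d) {
  d = std::fabs(d);
  d -= 180.0 * std::floor(d / 180.0);
  return d > 90.0 ? 180.0 - d : d;
}

// [[Rcpp::export]]
List bank_frame_scores(NumericVector px, NumericVector py, NumericVector ptheta,
                       IntegerVector frame, IntegerVector trial,
                       int n_frames, int n_trials,
                       NumericVector sx0, NumericVector sy0,
                       NumericVector sx1, NumericVector sy1,
                       NumericVector stheta, IntegerVector stemplate,
                       int K, double var_p, double var_t) {
  const int n_elem = px.size();
  const int n_seg = sx0.size();
  const int n_col = n_frames * n_trials;
  NumericMatrix pos(K, n_col), ori(K, n_col);

  const double cp = -0.5 * std::log(2.0 * M_PI * var_p);
  const double ct = -0.5 * std::log(2.0 * M_PI * var_t);
  const double ip = 1.0 / (2.0 * var_p);
  const double it = 1.0 / (2.0 * var_t);

  std::vector<double> best_d2(K);
  std::vector<double> best_th(K);

  for (int i = 0; i < n_elem; ++i) {
    const double x = px[i], y = py[i];
    for (int k = 0; k < K; ++k) { best_d2[k] = R_PosInf; best_th[k] = 0.0; }
    for (int s = 0; s < n_seg; ++s) {
      const int k = stemplate[s] - 1;
      const double d2 = pt_seg_dist2(x, y, sx0[s], sy0[s], sx1[s], sy1[s]);
      if (d2 < best_d2[k]) { best_d2[k] = d2; best_th[k] = stheta[s]; }
    }
    const int col = (trial[i] - 1) * n_frames + (frame[i] - 1);
    const double th = ptheta[i];
    for (int k = 0; k < K; ++k) {
      pos(k, col) += cp - best_d2[k] * ip;
      const double dth = fold_ori(th - best_th[k]);
      ori(k, col) += ct - dth * dth * it;
    }
  }
  return List::create(_["pos"] = pos, _["ori"] = ori);
}
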
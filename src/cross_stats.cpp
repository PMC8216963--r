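#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Epanechnikov kernel with bandwidth h, integrates to 1 over [-h, h]
static inline double epa(double u, double h) {
  double t = u / h;
  if (t <= -1.0 || t >= 1.0) return 0.0;
  return 0.75 * (1.0 - t * t) / h;
}

// Bivariate summary statistics for a focal pattern (xi, yi) and a second
// pattern (xj, yj) on the rectangle [0, W] x [0, H].
//
// pcf: kernel estimate of g_ij(r) at each radius,
//   ghat(r) = sum_{p in i, q in j} k_h(d_pq - r) w_pq / (2 pi r lambda_i lambda_j)
// with translation edge-correction weight w_pq = 1 / ((W - |dx|)(H - |dy|)),
// or w_pq = 1/(W*H) when translation correction is off.
//
// D: empirical fraction of focal points whose nearest j-neighbour lies
// within each radius (no edge correction).
static void cross_stats_core(const double* xi, const double* yi, int ni,
                             const double* xj, const double* yj, int nj,
                             double W, double H,
                             const double* r, const double* bw, int nr,
                             bool translation,
                             double* pcf_out, double* d_out) {
  std::vector<double> ksum(nr, 0.0);
  std::vector<int> dcount(nr, 0);
  double rmax = 0.0;
  for (int k = 0; k < nr; ++k) {
    double reach = r[k] + bw[k];
    if (reach > rmax) rmax = reach;
  }
  const double area = W * H;
  for (int p = 0; p < ni; ++p) {
    double dmin2 = R_PosInf;
    for (int q = 0; q < nj; ++q) {
      double dx = xi[p] - xj[q];
      double dy = yi[p] - yj[q];
      double d2 = dx * dx + dy * dy;
      if (d2 < dmin2) dmin2 = d2;
      if (d2 > rmax * rmax) continue;
      double d = std::sqrt(d2);
      double w = translation
        ? 1.0 / ((W - std::fabs(dx)) * (H - std::fabs(dy)))
        : 1.0 / area;
      for (int k = 0; k < nr; ++k) {
        double kv = epa(d - r[k], bw[k]);
        if (kv > 0.0) ksum[k] += kv * w;
      }
    }
    double dmin = std::sqrt(dmin2);
    for (int k = 0; k < nr; ++k)
      if (dmin <= r[k]) dcount[k] += 1;
  }
  const double lambda_i = ni / area;
  const double lambda_j = nj / area;
  for (int k = 0; k < nr; ++k) {
    pcf_out[k] = ksum[k] / (2.0 * M_PI * r[k] * lambda_i * lambda_j);
    d_out[k] = (double)dcount[k] / (double)ni;
  }
}

// [[Rcpp::export]]
List cpp_cross_stats(NumericVector xi, NumericVector yi,
                     NumericVector xj, NumericVector yj,
                     double W, double H,
                     NumericVector r, NumericVector bw, bool translation) {
  int nr = r.size();
  NumericVector pcf(nr), d(nr);
  cross_stats_core(xi.begin(), yi.begin(), xi.size(),
                   xj.begin(), yj.begin(), xj.size(),
                   W, H, r.begin(), bw.begin(), nr, translation,
                   pcf.begin(), d.begin());
  return List::create(_["pcf"] = pcf, _["D"] = d);
}

// Null ensemble: pattern i fixed, pattern j toroidally shifted by each
// (dx[s], dy[s]); returns one row per shift.
// [[Rcpp::export]]
List cpp_null_stats(NumericVector xi, NumericVector yi,
                    NumericVector xj, NumericVector yj,
                    double W, double H,
                    NumericVector r, NumericVector bw, bool translation,
                    NumericVector dx, NumericVector dy) {
  int nr = r.size(), nsim = dx.size(), nj = xj.size();
  NumericMatrix pcf(nsim, nr), d(nsim, nr);
  std::vector<double> xs(nj), ys(nj), prow(nr), drow(nr);
  for (int s = 0; s < nsim; ++s) {
    for (int q = 0; q < nj; ++q) {
      double x = xj[q] + dx[s];
      x -= W * std::floor(x / W);
      double y = yj[q] + dy[s];
      y -= H * std::floor(y / H);
      xs[q] = x;
      ys[q] = y;
    }
    cross_stats_core(xi.begin(), yi.begin(), xi.size(),
                     xs.data(), ys.data(), nj,
                     W, H, r.begin(), bw.begin(), nr, translation,
                     prow.data(), drow.data());
    for (int k = 0; k < nr; ++k) {
      pcf(s, k) = prow[k];
      d(s, k) = drow[k];
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["pcf"] = pcf, _["D"] = d);
}

// Neighbourhood pressure used by the interaction scenarios.
// type 1 (hierarchical): competitive-effect-weighted crowding, the sum over
//   heterospecific neighbours within radius of Phi(trait_q / tau):
//   neighbours high in the trait hierarchy exert more pressure, with tau
//   setting how steeply effect rises with rank. The caller scales the
//   result by the stem's own competitive-response sensitivity.
// type 2 (limiting similarity): sum over heterospecific neighbours within
//   radius of a Gaussian trait-similarity kernel exp(-(du/tau)^2).
// type 3 (rank-gap disadvantage): summed positive trait advantage of
//   heterospecific neighbours, sum_q max(trait_q - trait_p, 0).
// Conspecifics are excluded: the mechanisms of interest act between
// species, and conspecific crowding would swamp the cross-species signal.
// [[Rcpp::export]]
NumericVector cpp_neighbor_pressure(NumericVector x, NumericVector y,
                                    NumericVector trait, IntegerVector sp,
                                    double radius, int type, double tau) {
  int n = x.size();
  NumericVector out(n);
  double r2 = radius * radius;
  for (int p = 0; p < n; ++p) {
    double acc = 0.0;
    for (int q = 0; q < n; ++q) {
      if (q == p || sp[q] == sp[p]) continue;
      double dx = x[p] - x[q];
      if (std::fabs(dx) > radius) continue;
      double dy = y[p] - y[q];
      if (std::fabs(dy) > radius) continue;
      if (dx * dx + dy * dy > r2) continue;
      if (type == 1) {
        acc += R::pnorm(trait[q] / tau, 0.0, 1.0, 1, 0);
      } else if (type == 3) {
        if (trait[q] > trait[p]) acc += trait[q] - trait[p];
      } else {
        double du = (trait[q] - trait[p]) / tau;
        acc += std::exp(-du * du);
      }
    }
    out[p] = acc;
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
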
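#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Monte Carlo photon-packet transport through a voxel grid.
//
// Free paths are sampled as optical depths (-log xi) and walked through the
// grid voxel by voxel; the residual optical depth is carried across material
// boundaries so heterogeneous media need no rejection step. Interactions
// deposit W * mu_a / mu_tot locally and redirect the packet by
// Henyey-Greenstein sampling. Boundaries are index-matched: any packet
// leaving the grid, the cylinder mask (material 0) or the surface escapes.
// Russian roulette keeps the weight bookkeeping exact: kills add the lost
// weight to `residual`, survivals subtract the injected boost, so
// deposited + escaped + residual == launched up to rounding.

static inline double runif_open(void) {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

// [[Rcpp::export]]
List cpp_transport(IntegerVector ids, int nx, int ny, int nz,
                   NumericVector mua, NumericVector mus, NumericVector gfac,
                   double dx, double dy, NumericVector zb,
                   double x0, double y0, double cyl_radius,
                   int profile, double beam_radius, double n_photons,
                   double w_min, double roulette_p) {
  const R_xlen_t n_ph = (R_xlen_t) n_photons;
  std::vector<double> A((size_t) nx * ny * nz, 0.0);
  double escaped = 0.0, residual = 0.0;
  const double r2cyl = cyl_radius > 0 ? cyl_radius * cyl_radius : -1.0;
  const size_t sy = (size_t) nx, sz = (size_t) nx * ny;
  const double BIG = 1e30;

  GetRNGstate();
  for (R_xlen_t p = 0; p < n_ph; ++p) {
    if ((p & 8191) == 0) Rcpp::checkUserInterrupt();
    // launch at the surface, straight down, unit weight
    double xi = runif_open();
    double r = (profile == 1)
      ? beam_radius / M_SQRT2 * std::sqrt(-std::log(xi))
      : beam_radius * std::sqrt(xi);
    double phi = 2.0 * M_PI * unif_rand();
    double x = r * std::cos(phi), y = r * std::sin(phi), z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0, W = 1.0;
    int ix = (int) std::floor((x - x0) / dx);
    int iy = (int) std::floor((y - y0) / dy);
    int iz = 0;
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny ||
        (r2cyl > 0 && x * x + y * y > r2cyl)) {
      escaped += W;
      continue;
    }

    double tau = -std::log(runif_open());  // optical depth to next interaction
    bool alive = true;
    while (alive) {
      size_t vox = (size_t) ix + sy * iy + sz * iz;
      int m = ids[vox];
      if (m == 0) { escaped += W; break; }  // outside the tissue mask
      double mt = mua[m] + mus[m];

      // distance to the nearest voxel face along the flight direction
      double tx = ux > 0 ? (x0 + (ix + 1) * dx - x) / ux
                 : (ux < 0 ? (x0 + ix * dx - x) / ux : BIG);
      double ty = uy > 0 ? (y0 + (iy + 1) * dy - y) / uy
                 : (uy < 0 ? (y0 + iy * dy - y) / uy : BIG);
      double tz = uz > 0 ? (zb[iz + 1] - z) / uz
                 : (uz < 0 ? (zb[iz] - z) / uz : BIG);
      if (tx < 0) tx = 0; if (ty < 0) ty = 0; if (tz < 0) tz = 0;
      double tb = tx; int axis = 0;
      if (ty < tb) { tb = ty; axis = 1; }
      if (tz < tb) { tb = tz; axis = 2; }

      if (mt <= 0.0 || tb * mt < tau) {
        // free flight to the face; carry the residual optical depth
        x += ux * tb; y += uy * tb; z += uz * tb;
        if (mt > 0) tau -= tb * mt;
        if (axis == 0) ix += ux > 0 ? 1 : -1;
        else if (axis == 1) iy += uy > 0 ? 1 : -1;
        else iz += uz > 0 ? 1 : -1;
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
          escaped += W;
          break;
        }
        continue;
      }

      // interaction inside this voxel
      double s = tau / mt;
      x += ux * s; y += uy * s; z += uz * s;
      double dW = W * mua[m] / mt;
      A[vox] += dW;
      W -= dW;

      if (W < w_min) {  // Russian roulette, unbiased in expectation
        if (unif_rand() < roulette_p) {
          residual -= W * (1.0 / roulette_p - 1.0);
          W /= roulette_p;
        } else {
          residual += W;
          break;
        }
      }

      // Henyey-Greenstein deflection + uniform azimuth
      double g = gfac[m], ct;
      xi = runif_open();
      if (g != 0.0) {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      } else {
        ct = 2.0 * xi - 1.0;
      }
      double st = std::sqrt(1.0 - ct * ct);
      double psi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(psi), sp = std::sin(psi);
      double nux, nuy, nuz;
      if (std::fabs(uz) > 1.0 - 1e-6) {  // near-vertical special case
        nux = st * cp;
        nuy = st * sp;
        nuz = uz > 0 ? ct : -ct;
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        nuz = -st * cp * den + uz * ct;
      }
      double nrm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
      ux = nux / nrm; uy = nuy / nrm; uz = nuz / nrm;
      tau = -std::log(runif_open());
    }
  }
  PutRNGstate();

  return List::create(
    _["A"] = NumericVector(A.begin(), A.end()),
    _["escaped"] = escaped,
    _["residual"] = residual
  );
}
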
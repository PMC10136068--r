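#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Siddon-style exact ray/pixel intersection lengths for a flat-detector
// fan-beam geometry. Rays are emitted one column at a time in view-major
// order (ray j = view * n_det + det), so the result is directly the
// column-compressed storage of the transposed system matrix A^T (pixels x
// rays): column j holds the intersection lengths (mm) of ray j.
//
// Conventions: image center at isocenter, pixel (ix, iy) center at
// ((ix + 0.5 - n/2) * h, (iy + 0.5 - n/2) * h); linear pixel index
// ix + n * iy; views counter-clockwise with the source on the +x axis at
// view 0; detector index 0 at the most negative tangential offset.

// [[Rcpp::export]]
List siddon_fan_system(double sod, double sdd, int n_views,
                       double angular_range_deg, int n_det,
                       double det_pitch, int grid_n, double pixel_size) {
  const double W = grid_n * pixel_size;
  const double half = W / 2.0;
  const double h = pixel_size;
  const long long J = (long long)n_views * n_det;

  std::vector<int>    ii;
  std::vector<double> xx;
  std::vector<int>    pp((size_t)J + 1, 0);
  ii.reserve((size_t)J * (size_t)(2 * grid_n));
  xx.reserve((size_t)J * (size_t)(2 * grid_n));

  const double dview = angular_range_deg * M_PI / 180.0 / n_views;
  std::vector<std::pair<int, double> > col;
  col.reserve(4 * grid_n);

  long long j = 0;
  for (int v = 0; v < n_views; ++v) {
    const double beta = v * dview;
    const double cb = std::cos(beta), sb = std::sin(beta);
    const double sx = sod * cb, sy = sod * sb;        // source
    const double cxd = (sod - sdd) * cb;              // detector center
    const double cyd = (sod - sdd) * sb;
    const double eux = -sb, euy = cb;                 // detector tangent

    for (int k = 0; k < n_det; ++k, ++j) {
      const double off = (k + 0.5 - n_det / 2.0) * det_pitch;
      const double dx0 = cxd + off * eux - sx;
      const double dy0 = cyd + off * euy - sy;
      const double L = std::sqrt(dx0 * dx0 + dy0 * dy0);

      // clip the segment s + t*(d-s), t in [0,1], against the image box
      double tmin = 0.0, tmax = 1.0;
      bool hit = true;
      if (std::fabs(dx0) > 1e-12) {
        double ta = (-half - sx) / dx0, tb = (half - sx) / dx0;
        if (ta > tb) std::swap(ta, tb);
        tmin = std::max(tmin, ta); tmax = std::min(tmax, tb);
      } else if (sx < -half || sx > half) hit = false;
      if (std::fabs(dy0) > 1e-12) {
        double ta = (-half - sy) / dy0, tb = (half - sy) / dy0;
        if (ta > tb) std::swap(ta, tb);
        tmin = std::max(tmin, ta); tmax = std::min(tmax, tb);
      } else if (sy < -half || sy > half) hit = false;

      col.clear();
      if (hit && tmax > tmin + 1e-14) {
        const double dtx = (std::fabs(dx0) > 1e-12) ? h / std::fabs(dx0) : 1e300;
        const double dty = (std::fabs(dy0) > 1e-12) ? h / std::fabs(dy0) : 1e300;
        // first plane crossings strictly beyond tmin
        double tx = 1e300, ty = 1e300;
        if (dtx < 1e299) {
          double x_at = sx + tmin * dx0;
          double fidx = (x_at + half) / h;
          double next = (dx0 > 0) ? std::ceil(fidx - 1e-9) : std::floor(fidx + 1e-9);
          tx = ((next * h - half) - sx) / dx0;
          if (tx <= tmin + 1e-14) tx += dtx;
        }
        if (dty < 1e299) {
          double y_at = sy + tmin * dy0;
          double fidx = (y_at + half) / h;
          double next = (dy0 > 0) ? std::ceil(fidx - 1e-9) : std::floor(fidx + 1e-9);
          ty = ((next * h - half) - sy) / dy0;
          if (ty <= tmin + 1e-14) ty += dty;
        }
        double t = tmin;
        while (t < tmax - 1e-12) {
          double tn = std::min(std::min(tx, ty), tmax);
          const double len = (tn - t) * L;
          if (len > 1e-12) {
            const double mx = sx + 0.5 * (t + tn) * dx0;
            const double my = sy + 0.5 * (t + tn) * dy0;
            int ix = (int)std::floor((mx + half) / h);
            int iy = (int)std::floor((my + half) / h);
            if (ix >= 0 && ix < grid_n && iy >= 0 && iy < grid_n) {
              col.push_back(std::make_pair(ix + grid_n * iy, len));
            }
          }
          if (tx <= tn + 1e-14) tx += dtx;
          if (ty <= tn + 1e-14) ty += dty;
          t = tn;
        }
        std::sort(col.begin(), col.end());
      }
      for (size_t q = 0; q < col.size(); ++q) {
        ii.push_back(col[q].first);
        xx.push_back(col[q].second);
      }
      pp[(size_t)j + 1] = (int)ii.size();
    }
  }

  IntegerVector Ri(ii.size());
  NumericVector Rx(xx.size());
  std::copy(ii.begin(), ii.end(), Ri.begin());
  std::copy(xx.begin(), xx.end(), Rx.begin());
  IntegerVector Rp(pp.size());
  std::copy(pp.begin(), pp.end(), Rp.begin());

  return List::create(_["i"] = Ri, _["p"] = Rp, _["x"] = Rx,
                      _["nrow"] = grid_n * grid_n, _["ncol"] = (double)J);
}
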
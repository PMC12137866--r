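#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Zero-flux (mirrored-neighbour) 5-point Laplacian diffusion step, in place.
static void diffuse_step(std::vector<double> &C, int ny, int nx, double Ddt) {
  std::vector<double> L(static_cast<size_t>(ny) * nx);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      const size_t k = static_cast<size_t>(j) * ny + i;
      const double c = C[k];
      const double up    = (i > 0)      ? C[k - 1]  : c;
      const double down  = (i < ny - 1) ? C[k + 1]  : c;
      const double left  = (j > 0)      ? C[k - ny] : c;
      const double right = (j < nx - 1) ? C[k + ny] : c;
      L[k] = up + down + left + right - 4.0 * c;
    }
  }
  for (size_t k = 0; k < C.size(); ++k) C[k] += Ddt * L[k];
}

// Exponential leak + diffusion over dt (ns); explicit sub-steps with D*dt_sub <= 0.25.
// leak_cache holds per-pixel exp(-dt_sub/tau) factors keyed by dt_sub.
static void evolve(std::vector<double> &C, const double *tau, int ny, int nx,
                   double D, double dt,
                   std::map<double, std::vector<double> > &leak_cache) {
  if (dt <= 0.0) return;
  int nsub = 1;
  if (D > 0.0) nsub = std::max(1, (int)std::ceil(D * dt / 0.25));
  const double dts = dt / nsub;
  std::map<double, std::vector<double> >::iterator it = leak_cache.find(dts);
  if (it == leak_cache.end()) {
    std::vector<double> lk(C.size());
    for (size_t k = 0; k < C.size(); ++k)
      lk[k] = std::isfinite(tau[k]) ? std::exp(-dts / tau[k]) : 1.0;
    if (leak_cache.size() > 8) leak_cache.clear();
    it = leak_cache.insert(std::make_pair(dts, lk)).first;
  }
  const std::vector<double> &lk = it->second;
  for (int s = 0; s < nsub; ++s) {
    for (size_t k = 0; k < C.size(); ++k) C[k] *= lk[k];
    if (D > 0.0) diffuse_step(C, ny, nx, D * dts);
  }
}

// Gaussian-weighted local charge at (y, x); truncated at 3*sigma, weights
// renormalised over the in-bounds window.
static double local_charge(const std::vector<double> &C, int ny, int nx,
                           int y, int x, const std::vector<double> &w, int rad) {
  double num = 0.0, den = 0.0;
  for (int dj = -rad; dj <= rad; ++dj) {
    const int xx = x + dj;
    if (xx < 0 || xx >= nx) continue;
    for (int di = -rad; di <= rad; ++di) {
      const int yy = y + di;
      if (yy < 0 || yy >= ny) continue;
      const double ww = w[(di + rad) * (2 * rad + 1) + (dj + rad)];
      num += ww * C[static_cast<size_t>(xx) * ny + yy];
      den += ww;
    }
  }
  return den > 0.0 ? num / den : 0.0;
}

// [[Rcpp::export]]
NumericMatrix cpp_evolve(NumericMatrix C, NumericMatrix tau, double D, double dt) {
  const int ny = C.nrow(), nx = C.ncol();
  std::vector<double> cc(C.begin(), C.end());
  std::map<double, std::vector<double> > cache;
  evolve(cc, tau.begin(), ny, nx, D, dt, cache);
  NumericMatrix out(ny, nx);
  std::copy(cc.begin(), cc.end(), out.begin());
  return out;
}

// Core acquisition loop. Visits are 0-based pixel coordinates with absolute
// start times (ns). Dissipation is applied in batches of `batch` visits and at
// every time gap larger than the dwell (line/frame boundary). Deposition and
// detection both happen at the visited specimen pixel, offset by the per-frame
// drift. Returns per-visit detected counts (clipped to int16 range), final
// charge state, clip count and (optionally) the peak smoothed-charge trace.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix yield, NumericMatrix tau, NumericMatrix C0,
                  IntegerVector vx, IntegerVector vy, NumericVector vt,
                  IntegerVector vframe, double dwell,
                  IntegerVector drift_x, IntegerVector drift_y,
                  double q0, double D, double alpha, double sigma_local,
                  double noise_std, double gain, double offset,
                  int batch, bool discharge, double discharge_threshold,
                  double discharge_gain, double burn_q, bool record_peak) {
  const int ny = yield.nrow(), nx = yield.ncol();
  const int nvis = vx.size();
  std::vector<double> C(C0.begin(), C0.end());
  std::map<double, std::vector<double> > cache;

  const int rad = std::max(1, (int)std::ceil(3.0 * sigma_local));
  std::vector<double> w((2 * rad + 1) * (2 * rad + 1));
  for (int di = -rad; di <= rad; ++di)
    for (int dj = -rad; dj <= rad; ++dj)
      w[(di + rad) * (2 * rad + 1) + (dj + rad)] =
        std::exp(-(di * di + dj * dj) / (2.0 * sigma_local * sigma_local));

  NumericVector signal(nvis);
  std::vector<double> peaks;
  double t_evolved = nvis > 0 ? vt[0] : 0.0;
  int since_evolve = 0, nclip = 0;
  int last_sx = 0, last_sy = 0;
  RNGScope scope;

  for (int i = 0; i < nvis; ++i) {
    const int f = vframe[i];
    const bool gap = i > 0 && (vt[i] - vt[i - 1]) > dwell * (1.0 + 1e-9);
    const bool newframe = i > 0 && vframe[i] != vframe[i - 1];
    if (i > 0 && (since_evolve >= batch || gap)) {
      // beam parked at the previous position during an inter-frame pause
      if (newframe && burn_q > 0.0 && gap) {
        const double pause = vt[i] - vt[i - 1] - dwell;
        C[static_cast<size_t>(last_sx) * ny + last_sy] += burn_q * (pause / dwell);
      }
      evolve(C, tau.begin(), ny, nx, D, vt[i] - t_evolved, cache);
      t_evolved = vt[i];
      since_evolve = 0;
      if (record_peak) {
        double mx = 0.0;
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            const double v = local_charge(C, ny, nx, y, x, w, rad);
            if (v > mx) mx = v;
          }
        peaks.push_back(mx);
      }
    }
    int sx = vx[i] + drift_x[f], sy = vy[i] + drift_y[f];
    sx = std::min(std::max(sx, 0), nx - 1);
    sy = std::min(std::max(sy, 0), ny - 1);
    C[static_cast<size_t>(sx) * ny + sy] += q0;
    double ct = local_charge(C, ny, nx, sy, sx, w, rad);
    if (discharge && ct > discharge_threshold) {
      for (int dj = -rad; dj <= rad; ++dj)
        for (int di = -rad; di <= rad; ++di) {
          const int xx = sx + dj, yy = sy + di;
          if (xx >= 0 && xx < nx && yy >= 0 && yy < ny)
            C[static_cast<size_t>(xx) * ny + yy] = 0.0;
        }
      double s = gain * yield(sy, sx) + discharge_gain + offset;
      if (noise_std > 0.0) s += R::rnorm(0.0, noise_std);
      if (s > 32767.0) { s = 32767.0; ++nclip; }
      if (s < -32768.0) { s = -32768.0; ++nclip; }
      signal[i] = s;
    } else {
      double s = gain * yield(sy, sx) * std::exp(-alpha * ct) + offset;
      if (noise_std > 0.0) s += R::rnorm(0.0, noise_std);
      if (s > 32767.0) { s = 32767.0; ++nclip; }
      if (s < -32768.0) { s = -32768.0; ++nclip; }
      signal[i] = s;
    }
    last_sx = sx; last_sy = sy;
    ++since_evolve;
  }

  NumericMatrix Cout(ny, nx);
  std::copy(C.begin(), C.end(), Cout.begin());
  return List::create(_["signal"] = signal, _["charge"] = Cout,
                      _["n_clipped"] = nclip,
                      _["peak_trace"] = NumericVector(peaks.begin(), peaks.end()));
}

// Separable convolution with reflect (symmetric, edge-including) padding:
// columns (y direction) with ky, then rows (x direction) with kx. Kernels must
// have odd length.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix M, NumericVector ky, NumericVector kx) {
  const int ny = M.nrow(), nx = M.ncol();
  const int ry = (ky.size() - 1) / 2, rx = (kx.size() - 1) / 2;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      double s = 0.0;
      for (int t = -ry; t <= ry; ++t) {
        int ii = i + t;
        while (ii < 0 || ii >= ny) {   // fold until in range (radius may exceed ny)
          if (ii < 0) ii = -ii - 1;
          if (ii >= ny) ii = 2 * ny - ii - 1;
        }
        s += ky[t + ry] * M(ii, j);
      }
      tmp(i, j) = s;
    }
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      double s = 0.0;
      for (int t = -rx; t <= rx; ++t) {
        int jj = j + t;
        while (jj < 0 || jj >= nx) {
          if (jj < 0) jj = -jj - 1;
          if (jj >= nx) jj = 2 * nx - jj - 1;
        }
        s += kx[t + rx] * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return out;
}

// 8-connected components of a binary mask; labels assigned in row-major order
// of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  std::vector<int> sy, sx;
  int next = 0;
  for (int i = 0; i < ny; ++i) {
    for (int j = 0; j < nx; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      sy.clear(); sx.clear();
      sy.push_back(i); sx.push_back(j);
      lab(i, j) = next;
      while (!sy.empty()) {
        const int y = sy.back(), x = sx.back();
        sy.pop_back(); sx.pop_back();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int yy = y + di, xx = x + dj;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            if (mask(yy, xx) && lab(yy, xx) == 0) {
              lab(yy, xx) = next;
              sy.push_back(yy); sx.push_back(xx);
            }
          }
      }
    }
  }
  return lab;
}
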
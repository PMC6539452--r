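// Core numerical kernels: Siddon-style incremental ray traversal on a 2D
// voxel grid, the pinhole-response system matrix, the single-scatter
// multi-bin forward projector and the parallel-beam transmission projector.
//
// Conventions (shared with the R layer):
//   * world coordinates in mm, rotation centre at the origin;
//   * attenuation maps mu in 1/cm, so optical depth = sum(mu * len_mm) / 10;
//   * image matrices are nx x ny, first index = x, column-major as in R;
//   * apparatus frame: incident beam travels along +x, pinhole at (0, -L1),
//     detector line at y = -(L1 + L2) indexed left-to-right in x;
//   * view with angle a rotates the object by +a, i.e. in the object frame
//     the beam direction is R(-a) (1, 0) and the pinhole sits at R(-a) (0,-L1).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Optical depth along segment (x0,y0)->(x1,y1) through mu (1/cm) on a grid
// with origin corner (ox, oy) and square pixels of side ps (mm).
static double siddon_depth(const double *mu, int nx, int ny, double ps,
                           double ox, double oy,
                           double x0, double y0, double x1, double y1) {
  double dx = x1 - x0, dy = y1 - y0;
  double L = std::sqrt(dx * dx + dy * dy);
  if (L <= 0.0) return 0.0;
  // clip the parametric range [0,1] against the grid bounding box
  double tmin = 0.0, tmax = 1.0;
  double lox = ox, hix = ox + nx * ps, loy = oy, hiy = oy + ny * ps;
  if (std::fabs(dx) < 1e-12) {
    if (x0 < lox || x0 > hix) return 0.0;
  } else {
    double t0 = (lox - x0) / dx, t1 = (hix - x0) / dx;
    if (t0 > t1) std::swap(t0, t1);
    tmin = std::max(tmin, t0); tmax = std::min(tmax, t1);
  }
  if (std::fabs(dy) < 1e-12) {
    if (y0 < loy || y0 > hiy) return 0.0;
  } else {
    double t0 = (loy - y0) / dy, t1 = (hiy - y0) / dy;
    if (t0 > t1) std::swap(t0, t1);
    tmin = std::max(tmin, t0); tmax = std::min(tmax, t1);
  }
  if (tmin >= tmax) return 0.0;

  double t = tmin;
  double px = x0 + t * dx, py = y0 + t * dy;
  int ix = (int)std::floor((px - ox) / ps);
  int iy = (int)std::floor((py - oy) / ps);
  if (ix < 0) ix = 0; if (ix > nx - 1) ix = nx - 1;
  if (iy < 0) iy = 0; if (iy > ny - 1) iy = ny - 1;
  int stepx = dx > 0 ? 1 : -1, stepy = dy > 0 ? 1 : -1;
  double tMaxX = INF, tMaxY = INF, tDx = INF, tDy = INF;
  if (std::fabs(dx) >= 1e-12) {
    double bx = ox + (ix + (dx > 0 ? 1 : 0)) * ps;
    tMaxX = (bx - x0) / dx;
    tDx = ps / std::fabs(dx);
  }
  if (std::fabs(dy) >= 1e-12) {
    double by = oy + (iy + (dy > 0 ? 1 : 0)) * ps;
    tMaxY = (by - y0) / dy;
    tDy = ps / std::fabs(dy);
  }
  double acc = 0.0;
  while (true) {
    double tNext = std::min(std::min(tMaxX, tMaxY), tmax);
    double seg = (tNext - t) * L;
    if (seg > 0.0) acc += mu[ix + iy * nx] * seg;
    if (tNext >= tmax - 1e-15) break;
    if (tMaxX <= tMaxY) { ix += stepx; tMaxX += tDx; }
    else               { iy += stepy; tMaxY += tDy; }
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break;
    t = tNext;
  }
  return acc * 0.1;  // mm * (1/cm) -> dimensionless
}

// [[Rcpp::export]]
double cpp_line_depth(NumericMatrix mu, double ps, double ox, double oy,
                      double x0, double y0, double x1, double y1) {
  return siddon_depth(REAL(mu), mu.nrow(), mu.ncol(), ps, ox, oy, x0, y0, x1, y1);
}

// [[Rcpp::export]]
NumericVector cpp_line_depths(NumericMatrix mu, double ps, double ox, double oy,
                              NumericMatrix starts, NumericMatrix ends) {
  int n = starts.nrow();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = siddon_depth(REAL(mu), mu.nrow(), mu.ncol(), ps, ox, oy,
                          starts(k, 0), starts(k, 1), ends(k, 0), ends(k, 1));
  return out;
}

// Traversed cells and intersection lengths (mm) for one segment.
// [[Rcpp::export]]
List cpp_trace_cells(int nx, int ny, double ps, double ox, double oy,
                     double x0, double y0, double x1, double y1) {
  std::vector<int> vix, viy;
  std::vector<double> vlen;
  double dx = x1 - x0, dy = y1 - y0;
  double L = std::sqrt(dx * dx + dy * dy);
  if (L > 0.0) {
    double tmin = 0.0, tmax = 1.0;
    double lox = ox, hix = ox + nx * ps, loy = oy, hiy = oy + ny * ps;
    bool ok = true;
    if (std::fabs(dx) < 1e-12) { if (x0 < lox || x0 > hix) ok = false; }
    else {
      double t0 = (lox - x0) / dx, t1 = (hix - x0) / dx;
      if (t0 > t1) std::swap(t0, t1);
      tmin = std::max(tmin, t0); tmax = std::min(tmax, t1);
    }
    if (std::fabs(dy) < 1e-12) { if (y0 < loy || y0 > hiy) ok = false; }
    else {
      double t0 = (loy - y0) / dy, t1 = (hiy - y0) / dy;
      if (t0 > t1) std::swap(t0, t1);
      tmin = std::max(tmin, t0); tmax = std::min(tmax, t1);
    }
    if (ok && tmin < tmax) {
      double t = tmin;
      int ix = (int)std::floor((x0 + t * dx - ox) / ps);
      int iy = (int)std::floor((y0 + t * dy - oy) / ps);
      if (ix < 0) ix = 0; if (ix > nx - 1) ix = nx - 1;
      if (iy < 0) iy = 0; if (iy > ny - 1) iy = ny - 1;
      int stepx = dx > 0 ? 1 : -1, stepy = dy > 0 ? 1 : -1;
      double tMaxX = INF, tMaxY = INF, tDx = INF, tDy = INF;
      if (std::fabs(dx) >= 1e-12) {
        double bx = ox + (ix + (dx > 0 ? 1 : 0)) * ps;
        tMaxX = (bx - x0) / dx; tDx = ps / std::fabs(dx);
      }
      if (std::fabs(dy) >= 1e-12) {
        double by = oy + (iy + (dy > 0 ? 1 : 0)) * ps;
        tMaxY = (by - y0) / dy; tDy = ps / std::fabs(dy);
      }
      while (true) {
        double tNext = std::min(std::min(tMaxX, tMaxY), tmax);
        double seg = (tNext - t) * L;
        if (seg > 1e-12) { vix.push_back(ix + 1); viy.push_back(iy + 1); vlen.push_back(seg); }
        if (tNext >= tmax - 1e-15) break;
        if (tMaxX <= tMaxY) { ix += stepx; tMaxX += tDx; }
        else               { iy += stepy; tMaxY += tDy; }
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break;
        t = tNext;
      }
    }
  }
  return List::create(_["ix"] = wrap(vix), _["iy"] = wrap(viy),
                      _["length_mm"] = wrap(vlen));
}

// Geometric coupling of one apparatus-frame point to the detector pixels:
// ideal (infinitely thin) rectangular pinhole of width aw / height ah at
// (0, -L1); detector of npix pixels of width pw at y = -(L1 + L2).
// Appends (pixel index 0-based, fraction of the aperture solid angle) pairs.
static int pinhole_couple(double vx, double vy, double L1, double L2,
                          int npix, double pw, double aw, double ah,
                          int *pix, double *val) {
  double tv = vy + L1;          // axial distance voxel -> pinhole plane
  if (tv <= 1e-6) return 0;     // behind (or in) the pinhole plane
  double uc = -vx * L2 / tv;                  // image of the point
  double wimg = aw * (tv + L2) / tv;          // penumbra width of the aperture
  double r2 = vx * vx + tv * tv;
  double omega = aw * ah * (tv / std::sqrt(r2)) / (4.0 * M_PI * r2);
  double half = 0.5 * npix * pw;
  double lo = uc - 0.5 * wimg, hi = uc + 0.5 * wimg;
  int ilo = (int)std::floor((lo + half) / pw);
  int ihi = (int)std::floor((hi + half) / pw);
  if (ilo < 0) ilo = 0;
  if (ihi > npix - 1) ihi = npix - 1;
  int n = 0;
  for (int i = ilo; i <= ihi; ++i) {
    double plo = -half + i * pw, phi = plo + pw;
    double ov = std::min(phi, hi) - std::max(plo, lo);
    if (ov > 0.0) { pix[n] = i; val[n] = omega * ov / wimg; ++n; }
  }
  return n;
}

// [[Rcpp::export]]
List cpp_system_matrix(NumericMatrix mu_inc, NumericMatrix mu_xrf,
                       double ps, double ox, double oy,
                       NumericVector angles, double L1, double L2,
                       int npix, double pw, double aw, double ah) {
  int nx = mu_inc.nrow(), ny = mu_inc.ncol(), nv = angles.size();
  const double *mi = REAL(mu_inc), *mx = REAL(mu_xrf);
  double reach = 2.0 * (std::fabs(ox) + std::fabs(oy) + (nx + ny) * ps) + L1;
  std::vector<int> ri, ci;
  std::vector<double> vv;
  ri.reserve(nv * nx * ny / 4); ci.reserve(nv * nx * ny / 4); vv.reserve(nv * nx * ny / 4);
  int pixbuf[64]; double valbuf[64];
  for (int v = 0; v < nv; ++v) {
    double a = angles[v], ca = std::cos(a), sa = std::sin(a);
    double bdx = ca, bdy = -sa;                 // beam direction, object frame
    double phx = -L1 * sa, phy = -L1 * ca;      // pinhole, object frame
    for (int iy = 0; iy < ny; ++iy) {
      double vy0 = oy + (iy + 0.5) * ps;
      for (int ix = 0; ix < nx; ++ix) {
        double vx0 = ox + (ix + 0.5) * ps;
        // apparatus-frame position of the (rotated) voxel
        double rx = ca * vx0 - sa * vy0, ry = sa * vx0 + ca * vy0;
        int n = pinhole_couple(rx, ry, L1, L2, npix, pw, aw, ah, pixbuf, valbuf);
        if (n == 0) continue;
        double din = siddon_depth(mi, nx, ny, ps, ox, oy,
                                  vx0 - reach * bdx, vy0 - reach * bdy, vx0, vy0);
        double dem = siddon_depth(mx, nx, ny, ps, ox, oy, vx0, vy0, phx, phy);
        double att = std::exp(-din - dem);
        int col = ix + iy * nx + 1;
        for (int k = 0; k < n; ++k) {
          ri.push_back(v * npix + pixbuf[k] + 1);
          ci.push_back(col);
          vv.push_back(valbuf[k] * att);
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci), _["x"] = wrap(vv));
}

static double interp_w(const double *theta, const double *w, int n, double th) {
  if (th <= theta[0]) return w[0];
  if (th >= theta[n - 1]) return w[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int m = (lo + hi) / 2; if (theta[m] <= th) lo = m; else hi = m; }
  double f = (th - theta[lo]) / (theta[hi] - theta[lo]);
  return w[lo] + f * (w[hi] - w[lo]);
}

// Noiseless expectations of the three-bin acquisition: fluorescence counts
// (middle bin only) and single-scatter counts per bin.
//   q_em:  per-voxel fluorescence emission density (already includes fluence,
//          exposure, voxel area and fluorescence yield)
//   q_sc:  per-voxel scatter emission density (electron-density weight times
//          the scatter amplitude)
//   w_tab: ntheta x 3 relative scattered-photon weights per bin vs angle
// [[Rcpp::export]]
List cpp_sim_xfct(NumericMatrix q_em, NumericMatrix q_sc,
                  NumericMatrix mu_inc, NumericMatrix mu_xrf,
                  NumericMatrix mu_b1, NumericMatrix mu_b2, NumericMatrix mu_b3,
                  double ps, double ox, double oy,
                  NumericVector angles, double L1, double L2,
                  int npix, double pw, double aw, double ah,
                  NumericVector theta_grid, NumericMatrix w_tab) {
  int nx = q_em.nrow(), ny = q_em.ncol(), nv = angles.size();
  int nth = theta_grid.size();
  const double *mi = REAL(mu_inc), *mx = REAL(mu_xrf);
  const double *mb[3] = { REAL(mu_b1), REAL(mu_b2), REAL(mu_b3) };
  NumericMatrix fl(nv, npix), s1(nv, npix), s2(nv, npix), s3(nv, npix);
  NumericMatrix *sc[3] = { &s1, &s2, &s3 };
  double reach = 2.0 * (std::fabs(ox) + std::fabs(oy) + (nx + ny) * ps) + L1;
  int pixbuf[64]; double valbuf[64];
  for (int v = 0; v < nv; ++v) {
    double a = angles[v], ca = std::cos(a), sa = std::sin(a);
    double bdx = ca, bdy = -sa;
    double phx = -L1 * sa, phy = -L1 * ca;
    for (int iy = 0; iy < ny; ++iy) {
      double vy0 = oy + (iy + 0.5) * ps;
      for (int ix = 0; ix < nx; ++ix) {
        double qe = q_em(ix, iy), qs = q_sc(ix, iy);
        if (qe <= 0.0 && qs <= 0.0) continue;
        double vx0 = ox + (ix + 0.5) * ps;
        double rx = ca * vx0 - sa * vy0, ry = sa * vx0 + ca * vy0;
        int n = pinhole_couple(rx, ry, L1, L2, npix, pw, aw, ah, pixbuf, valbuf);
        if (n == 0) continue;
        double din = siddon_depth(mi, nx, ny, ps, ox, oy,
                                  vx0 - reach * bdx, vy0 - reach * bdy, vx0, vy0);
        double ain = std::exp(-din);
        if (qe > 0.0) {
          double dem = siddon_depth(mx, nx, ny, ps, ox, oy, vx0, vy0, phx, phy);
          double w = qe * ain * std::exp(-dem);
          for (int k = 0; k < n; ++k) fl(v, pixbuf[k]) += w * valbuf[k];
        }
        if (qs > 0.0) {
          // scatter angle between the beam direction and voxel -> pinhole
          double ux = phx - vx0, uy = phy - vy0;
          double un = std::sqrt(ux * ux + uy * uy);
          double cth = (ux * bdx + uy * bdy) / un;
          if (cth > 1.0) cth = 1.0; if (cth < -1.0) cth = -1.0;
          double th = std::acos(cth);
          for (int b = 0; b < 3; ++b) {
            double dem = siddon_depth(mb[b], nx, ny, ps, ox, oy, vx0, vy0, phx, phy);
            double wb = interp_w(REAL(theta_grid), &w_tab(0, b), nth, th);
            double w = qs * ain * wb * std::exp(-dem);
            for (int k = 0; k < n; ++k) (*sc[b])(v, pixbuf[k]) += w * valbuf[k];
          }
        }
      }
    }
  }
  return List::create(_["fluorescence"] = fl,
                      _["scatter"] = List::create(s1, s2, s3));
}

// Parallel-beam line-integral sinogram (optical depth per ray).
// [[Rcpp::export]]
NumericMatrix cpp_parallel_sinogram(NumericMatrix mu, double ps, double ox, double oy,
                                    NumericVector angles, NumericVector offsets) {
  int nv = angles.size(), nr = offsets.size();
  int nx = mu.nrow(), ny = mu.ncol();
  const double *m = REAL(mu);
  double reach = 2.0 * (std::fabs(ox) + std::fabs(oy) + (nx + ny) * ps);
  NumericMatrix out(nv, nr);
  for (int v = 0; v < nv; ++v) {
    double a = angles[v];
    double ux = std::cos(a), uy = std::sin(a);    // ray direction
    double nxv = -uy, nyv = ux;                   // offset direction
    for (int r = 0; r < nr; ++r) {
      double cx = offsets[r] * nxv, cy = offsets[r] * nyv;
      out(v, r) = siddon_depth(m, nx, ny, ps, ox, oy,
                               cx - reach * ux, cy - reach * uy,
                               cx + reach * ux, cy + reach * uy);
    }
  }
  return out;
}
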
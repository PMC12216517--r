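#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Volumes are column-major arrays (nx, ny, nz); voxel (i,j,k) sits at
// physical position origin + (i,j,k) * spacing (voxel-center convention,
// 0-based indices). All transforms and displacements are in physical mm.

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

struct Grid {
  const double *v;
  int nx, ny, nz;
  double sx, sy, sz, ox, oy, oz;
  Grid(const NumericVector &vol, const NumericVector &spacing,
       const NumericVector &origin) {
    v = REAL(vol);
    IntegerVector d = vol.attr("dim");
    nx = d[0]; ny = d[1]; nz = d[2];
    sx = spacing[0]; sy = spacing[1]; sz = spacing[2];
    ox = origin[0]; oy = origin[1]; oz = origin[2];
  }
  inline double at(int i, int j, int k) const {
    return v[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  }
  // trilinear sample at physical point; points within half a voxel outside
  // the grid are clamped, farther points return `fill`
  inline double linear(double px, double py, double pz, double fill) const {
    double x = (px - ox) / sx, y = (py - oy) / sy, z = (pz - oz) / sz;
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
      return fill;
    x = clampd(x, 0.0, nx - 1.0);
    y = clampd(y, 0.0, ny - 1.0);
    z = clampd(z, 0.0, nz - 1.0);
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--; if (j0 == ny - 1) j0--; if (k0 == nz - 1) k0--;
    if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double c00 = at(i0, j0, k0) * (1 - fx) + at(i1, j0, k0) * fx;
    double c10 = at(i0, j1, k0) * (1 - fx) + at(i1, j1, k0) * fx;
    double c01 = at(i0, j0, k1) * (1 - fx) + at(i1, j0, k1) * fx;
    double c11 = at(i0, j1, k1) * (1 - fx) + at(i1, j1, k1) * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
  }
  // trilinear value and spatial gradient (per mm); gradient is 0 outside
  inline double linear_grad(double px, double py, double pz, double fill,
                            double grad[3]) const {
    grad[0] = grad[1] = grad[2] = 0.0;
    double x = (px - ox) / sx, y = (py - oy) / sy, z = (pz - oz) / sz;
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
      return fill;
    x = clampd(x, 0.0, nx - 1.0);
    y = clampd(y, 0.0, ny - 1.0);
    z = clampd(z, 0.0, nz - 1.0);
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--; if (j0 == ny - 1) j0--; if (k0 == nz - 1) k0--;
    if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double v000 = at(i0, j0, k0), v100 = at(i1, j0, k0);
    double v010 = at(i0, j1, k0), v110 = at(i1, j1, k0);
    double v001 = at(i0, j0, k1), v101 = at(i1, j0, k1);
    double v011 = at(i0, j1, k1), v111 = at(i1, j1, k1);
    double c00 = v000 * (1 - fx) + v100 * fx;
    double c10 = v010 * (1 - fx) + v110 * fx;
    double c01 = v001 * (1 - fx) + v101 * fx;
    double c11 = v011 * (1 - fx) + v111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    grad[0] = (((v100 - v000) * (1 - fy) + (v110 - v010) * fy) * (1 - fz) +
               ((v101 - v001) * (1 - fy) + (v111 - v011) * fy) * fz) / sx;
    grad[1] = ((c10 - c00) * (1 - fz) + (c11 - c01) * fz) / sy;
    grad[2] = (c1 - c0) / sz;
    return c0 * (1 - fz) + c1 * fz;
  }
  inline double nearest(double px, double py, double pz, double fill) const {
    double x = (px - ox) / sx, y = (py - oy) / sy, z = (pz - oz) / sz;
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return fill;
    return at(i, j, k);
  }
};

// cubic B-spline basis weights for fractional offset t in [0,1)
static inline void bspline_w(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

struct FFD {
  const double *c;
  int nx, ny, nz;          // control grid dims
  double hx, hy, hz, ox, oy, oz;
  bool empty;
  FFD() : c(nullptr), empty(true) {}
  FFD(const NumericVector &coef, const NumericVector &gorigin,
      const NumericVector &gspacing) {
    c = REAL(coef);
    IntegerVector d = coef.attr("dim");
    nx = d[0]; ny = d[1]; nz = d[2];
    hx = gspacing[0]; hy = gspacing[1]; hz = gspacing[2];
    ox = gorigin[0]; oy = gorigin[1]; oz = gorigin[2];
    empty = false;
  }
  inline double coef_at(int i, int j, int k, int d) const {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
    return c[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * (k + (R_xlen_t)nz * d))];
  }
  inline void disp(double px, double py, double pz, double out[3]) const {
    out[0] = out[1] = out[2] = 0.0;
    if (empty) return;
    double tx = (px - ox) / hx, ty = (py - oy) / hy, tz = (pz - oz) / hz;
    int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
    double wx[4], wy[4], wz[4];
    bspline_w(tx - ix, wx); bspline_w(ty - iy, wy); bspline_w(tz - iz, wz);
    for (int a = 0; a < 4; a++) {
      int ci = ix - 1 + a;
      for (int b = 0; b < 4; b++) {
        int cj = iy - 1 + b;
        double wab = wx[a] * wy[b];
        for (int g = 0; g < 4; g++) {
          int ck = iz - 1 + g;
          double w = wab * wz[g];
          if (w == 0.0) continue;
          out[0] += w * coef_at(ci, cj, ck, 0);
          out[1] += w * coef_at(ci, cj, ck, 1);
          out[2] += w * coef_at(ci, cj, ck, 2);
        }
      }
    }
  }
};

struct Affine {
  double A[9]; // row-major
  double t[3];
  Affine(const NumericMatrix &Am, const NumericVector &tv) {
    for (int r = 0; r < 3; r++)
      for (int cc = 0; cc < 3; cc++) A[3 * r + cc] = Am(r, cc);
    for (int r = 0; r < 3; r++) t[r] = tv[r];
  }
  inline void apply(const double p[3], double out[3]) const {
    for (int r = 0; r < 3; r++)
      out[r] = A[3 * r] * p[0] + A[3 * r + 1] * p[1] + A[3 * r + 2] * p[2] + t[r];
  }
};

// total transform G(x) = A x + t + u_ffd(x)
static inline void total_map(const Affine &af, const FFD &ffd,
                             const double p[3], double out[3]) {
  double u[3];
  af.apply(p, out);
  ffd.disp(p[0], p[1], p[2], u);
  out[0] += u[0]; out[1] += u[1]; out[2] += u[2];
}

// [[Rcpp::export]]
NumericVector cpp_sample(NumericVector vol, NumericVector spacing,
                         NumericVector origin, NumericMatrix pts,
                         double fill, bool nearest) {
  Grid g(vol, spacing, origin);
  int n = pts.nrow();
  NumericVector out(n);
  for (int s = 0; s < n; s++)
    out[s] = nearest ? g.nearest(pts(s, 0), pts(s, 1), pts(s, 2), fill)
                     : g.linear(pts(s, 0), pts(s, 1), pts(s, 2), fill);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ffd_disp(NumericVector coef, NumericVector gorigin,
                           NumericVector gspacing, NumericMatrix pts) {
  FFD ffd(coef, gorigin, gspacing);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  double p[3], u[3];
  for (int s = 0; s < n; s++) {
    p[0] = pts(s, 0); p[1] = pts(s, 1); p[2] = pts(s, 2);
    ffd.disp(p[0], p[1], p[2], u);
    out(s, 0) = u[0]; out(s, 1) = u[1]; out(s, 2) = u[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_transform(NumericMatrix A, NumericVector t,
                                  Nullable<NumericVector> coef,
                                  NumericVector gorigin, NumericVector gspacing,
                                  NumericMatrix pts) {
  Affine af(A, t);
  FFD ffd;
  NumericVector cf;
  if (coef.isNotNull()) { cf = coef.get(); ffd = FFD(cf, gorigin, gspacing); }
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  double p[3], y[3];
  for (int s = 0; s < n; s++) {
    p[0] = pts(s, 0); p[1] = pts(s, 1); p[2] = pts(s, 2);
    total_map(af, ffd, p, y);
    out(s, 0) = y[0]; out(s, 1) = y[1]; out(s, 2) = y[2];
  }
  return out;
}

// Solve G(y) = x per point by fixed-point iteration
// y <- Ainv (x - t - u(y)); returns solution points and residuals |G(y)-x|.
// [[Rcpp::export]]
List cpp_invert_points(NumericMatrix A, NumericVector t,
                       Nullable<NumericVector> coef,
                       NumericVector gorigin, NumericVector gspacing,
                       NumericMatrix pts, int maxit, double tol) {
  Affine af(A, t);
  FFD ffd;
  NumericVector cf;
  if (coef.isNotNull()) { cf = coef.get(); ffd = FFD(cf, gorigin, gspacing); }
  // invert the 3x3 affine part
  double a[9];
  for (int r = 0; r < 9; r++) a[r] = af.A[r];
  double det = a[0] * (a[4] * a[8] - a[5] * a[7]) -
               a[1] * (a[3] * a[8] - a[5] * a[6]) +
               a[2] * (a[3] * a[7] - a[4] * a[6]);
  if (std::fabs(det) < 1e-12) stop("affine component is singular");
  double inv[9];
  inv[0] = (a[4] * a[8] - a[5] * a[7]) / det;
  inv[1] = (a[2] * a[7] - a[1] * a[8]) / det;
  inv[2] = (a[1] * a[5] - a[2] * a[4]) / det;
  inv[3] = (a[5] * a[6] - a[3] * a[8]) / det;
  inv[4] = (a[0] * a[8] - a[2] * a[6]) / det;
  inv[5] = (a[2] * a[3] - a[0] * a[5]) / det;
  inv[6] = (a[3] * a[7] - a[4] * a[6]) / det;
  inv[7] = (a[1] * a[6] - a[0] * a[7]) / det;
  inv[8] = (a[0] * a[4] - a[1] * a[3]) / det;

  int n = pts.nrow();
  NumericMatrix out(n, 3);
  NumericVector res(n);
  double x[3], y[3], u[3], rhs[3], gy[3];
  for (int s = 0; s < n; s++) {
    x[0] = pts(s, 0); x[1] = pts(s, 1); x[2] = pts(s, 2);
    // initial guess: affine-only inverse
    for (int r = 0; r < 3; r++) rhs[r] = x[r] - af.t[r];
    for (int r = 0; r < 3; r++)
      y[r] = inv[3 * r] * rhs[0] + inv[3 * r + 1] * rhs[1] + inv[3 * r + 2] * rhs[2];
    double rr = std::numeric_limits<double>::infinity();
    for (int it = 0; it < maxit; it++) {
      ffd.disp(y[0], y[1], y[2], u);
      for (int r = 0; r < 3; r++) rhs[r] = x[r] - af.t[r] - u[r];
      double yn[3];
      for (int r = 0; r < 3; r++)
        yn[r] = inv[3 * r] * rhs[0] + inv[3 * r + 1] * rhs[1] + inv[3 * r + 2] * rhs[2];
      y[0] = yn[0]; y[1] = yn[1]; y[2] = yn[2];
      total_map(af, ffd, y, gy);
      rr = std::sqrt((gy[0] - x[0]) * (gy[0] - x[0]) +
                     (gy[1] - x[1]) * (gy[1] - x[1]) +
                     (gy[2] - x[2]) * (gy[2] - x[2]));
      if (rr <= tol) break;
    }
    out(s, 0) = y[0]; out(s, 1) = y[1]; out(s, 2) = y[2];
    res[s] = rr;
  }
  return List::create(_["points"] = out, _["residual"] = res);
}

// Resample a moving volume onto an output grid through G: out(x) = M(G(x)).
// [[Rcpp::export]]
NumericVector cpp_warp_volume(NumericVector moving, NumericVector mspacing,
                              NumericVector morigin, NumericMatrix A,
                              NumericVector t, Nullable<NumericVector> coef,
                              NumericVector gorigin, NumericVector gspacing,
                              IntegerVector odim, NumericVector ospacing,
                              NumericVector oorigin, double fill, bool nearest) {
  Grid m(moving, mspacing, morigin);
  Affine af(A, t);
  FFD ffd;
  NumericVector cf;
  if (coef.isNotNull()) { cf = coef.get(); ffd = FFD(cf, gorigin, gspacing); }
  int nx = odim[0], ny = odim[1], nz = odim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = odim;
  double p[3], y[3];
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; k++) {
    p[2] = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < ny; j++) {
      p[1] = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < nx; i++) {
        p[0] = oorigin[0] + i * ospacing[0];
        total_map(af, ffd, p, y);
        out[idx++] = nearest ? m.nearest(y[0], y[1], y[2], fill)
                             : m.linear(y[0], y[1], y[2], fill);
      }
    }
  }
  return out;
}

// ---------------- NMI metric -----------------------------------------------

struct Hist {
  std::vector<double> H;
  int nb;
  double total;
  Hist(int nbins) : H((size_t)nbins * nbins, 0.0), nb(nbins), total(0.0) {}
  inline void add(int fb, double mpos, double w) {
    int b0 = (int)std::floor(mpos);
    if (b0 >= nb - 1) b0 = nb - 2;
    if (b0 < 0) b0 = 0;
    double f = mpos - b0;
    if (f < 0) f = 0; if (f > 1) f = 1;
    H[(size_t)fb * nb + b0] += w * (1 - f);
    H[(size_t)fb * nb + b0 + 1] += w * f;
    total += w;
  }
  double nmi() const {
    std::vector<double> pf(nb, 0.0), pm(nb, 0.0);
    for (int i = 0; i < nb; i++)
      for (int j = 0; j < nb; j++) {
        double v = H[(size_t)i * nb + j];
        pf[i] += v; pm[j] += v;
      }
    double hf = 0, hm = 0, hfm = 0;
    for (int i = 0; i < nb; i++) {
      if (pf[i] > 0) { double p = pf[i] / total; hf -= p * std::log(p); }
      if (pm[i] > 0) { double p = pm[i] / total; hm -= p * std::log(p); }
    }
    for (size_t s = 0; s < H.size(); s++)
      if (H[s] > 0) { double p = H[s] / total; hfm -= p * std::log(p); }
    if (hfm <= 0) return 2.0; // identical degenerate: max NMI
    return (hf + hm) / hfm;
  }
};

static inline double mpos_of(double val, double mmin, double mrange, int nb) {
  double v = (val - mmin) / mrange * (nb - 1);
  return clampd(v, 0.0, nb - 1.0);
}

// NMI of fixed sample bins vs moving volume sampled through G.
// [[Rcpp::export]]
double cpp_nmi(IntegerVector fixedBins, NumericMatrix pts, NumericVector moving,
               NumericVector mspacing, NumericVector morigin, NumericMatrix A,
               NumericVector t, Nullable<NumericVector> coef,
               NumericVector gorigin, NumericVector gspacing, int nbins,
               double mmin, double mmax, double fill) {
  Grid m(moving, mspacing, morigin);
  Affine af(A, t);
  FFD ffd;
  NumericVector cf;
  if (coef.isNotNull()) { cf = coef.get(); ffd = FFD(cf, gorigin, gspacing); }
  int n = pts.nrow();
  double mrange = std::max(mmax - mmin, 1e-12);
  Hist h(nbins);
  double p[3], y[3];
  for (int s = 0; s < n; s++) {
    p[0] = pts(s, 0); p[1] = pts(s, 1); p[2] = pts(s, 2);
    total_map(af, ffd, p, y);
    double v = m.linear(y[0], y[1], y[2], fill);
    h.add(fixedBins[s], mpos_of(v, mmin, mrange, nbins), 1.0);
  }
  return h.nmi();
}

// ---------------- FFD optimizer --------------------------------------------

// Bending-energy surrogate on the control lattice: mean squared second
// difference of the coefficients along each axis (mm^2). Penalizing it keeps
// the free-form field smooth and suppresses metric-gaming oscillations
// (e.g., axial shuffling along a symmetry axis).
struct Bend {
  const double *C;
  int nx, ny, nz;
  R_xlen_t nc;
  Bend(const double *C_, int nx_, int ny_, int nz_)
      : C(C_), nx(nx_), ny(ny_), nz(nz_), nc((R_xlen_t)nx_ * ny_ * nz_) {}
  inline double cat(int i, int j, int k, int d) const {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
    return C[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k) + nc * d];
  }
  double total() const {
    double s = 0;
    for (int d = 0; d < 3; d++)
      for (int k = 0; k < nz; k++)
        for (int j = 0; j < ny; j++)
          for (int i = 0; i < nx; i++) {
            double c0 = cat(i, j, k, d);
            double dx = cat(i + 1, j, k, d) - 2 * c0 + cat(i - 1, j, k, d);
            double dy = cat(i, j + 1, k, d) - 2 * c0 + cat(i, j - 1, k, d);
            double dz = cat(i, j, k + 1, d) - 2 * c0 + cat(i, j, k - 1, d);
            s += dx * dx + dy * dy + dz * dz;
          }
    return s / (3.0 * nc);
  }
  // change in total() when control (i,j,k,d) moves by delta
  double delta(int i, int j, int k, int d, double del) const {
    double s0 = 0, s1 = 0;
    for (int t = -2; t <= 2; t++) {
      // terms along each axis whose stencil includes (i,j,k)
      int ii = i + t, jj = j + t, kk = k + t;
      if (ii >= 0 && ii < nx) {
        double c = cat(ii + 1, j, k, d) - 2 * cat(ii, j, k, d) + cat(ii - 1, j, k, d);
        double w = (ii + 1 == i || ii - 1 == i) ? 1 : (ii == i ? -2 : 0);
        if (w != 0) { s0 += c * c; double cn = c + w * del; s1 += cn * cn; }
      }
      if (jj >= 0 && jj < ny) {
        double c = cat(i, jj + 1, k, d) - 2 * cat(i, jj, k, d) + cat(i, jj - 1, k, d);
        double w = (jj + 1 == j || jj - 1 == j) ? 1 : (jj == j ? -2 : 0);
        if (w != 0) { s0 += c * c; double cn = c + w * del; s1 += cn * cn; }
      }
      if (kk >= 0 && kk < nz) {
        double c = cat(i, j, kk + 1, d) - 2 * cat(i, j, kk, d) + cat(i, j, kk - 1, d);
        double w = (kk + 1 == k || kk - 1 == k) ? 1 : (kk == k ? -2 : 0);
        if (w != 0) { s0 += c * c; double cn = c + w * del; s1 += cn * cn; }
      }
    }
    return (s1 - s0) / (3.0 * nc);
  }
};

// Optimize b-spline control-point displacements against NMI (metric = 0) or
// mean SSD (metric = 1), minus lambda x bending energy. Two phases per step
// size: synchronized passes (probe every control incrementally, assemble the
// improving probes into one global direction, line-search it) followed by
// greedy per-control sweeps for local refinement.
// [[Rcpp::export]]
List cpp_ffd_optimize(IntegerVector fixedBins, NumericVector fixedVals,
                      NumericMatrix pts, NumericVector moving,
                      NumericVector mspacing, NumericVector morigin,
                      NumericMatrix A, NumericVector t, NumericVector coef0,
                      NumericVector gorigin, NumericVector gspacing,
                      NumericVector steps, int passes, int sync_passes,
                      int nbins, double mmin, double mmax, double fill,
                      int metric, double lambda, IntegerVector axes) {
  Grid m(moving, mspacing, morigin);
  Affine af(A, t);
  NumericVector coef = clone(coef0);
  IntegerVector cd = coef.attr("dim");
  int ncx = cd[0], ncy = cd[1], ncz = cd[2];
  double *C = REAL(coef);
  FFD ffd(coef, gorigin, gspacing);
  int n = pts.nrow();
  double mrange = std::max(mmax - mmin, 1e-12);
  Bend bend(C, ncx, ncy, ncz);

  std::vector<double> bx(n), by(n), bz(n), ux(n), uy(n), uz(n), mval(n);
  double p[3], y[3], u[3];
  for (int s = 0; s < n; s++) {
    p[0] = pts(s, 0); p[1] = pts(s, 1); p[2] = pts(s, 2);
    af.apply(p, y);
    bx[s] = y[0]; by[s] = y[1]; bz[s] = y[2];
    ffd.disp(p[0], p[1], p[2], u);
    ux[s] = u[0]; uy[s] = u[1]; uz[s] = u[2];
    mval[s] = m.linear(y[0] + u[0], y[1] + u[1], y[2] + u[2], fill);
  }

  R_xlen_t nctrl = (R_xlen_t)ncx * ncy * ncz;
  std::vector<std::vector<std::pair<int, float> > > sup(nctrl);
  for (int s = 0; s < n; s++) {
    double tx = (pts(s, 0) - gorigin[0]) / gspacing[0];
    double ty = (pts(s, 1) - gorigin[1]) / gspacing[1];
    double tz = (pts(s, 2) - gorigin[2]) / gspacing[2];
    int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
    double wx[4], wy[4], wz[4];
    bspline_w(tx - ix, wx); bspline_w(ty - iy, wy); bspline_w(tz - iz, wz);
    for (int a = 0; a < 4; a++) {
      int ci = ix - 1 + a;
      if (ci < 0 || ci >= ncx) continue;
      for (int b = 0; b < 2 + 2; b++) {
        int cj = iy - 1 + b;
        if (cj < 0 || cj >= ncy) continue;
        for (int g = 0; g < 4; g++) {
          int ck = iz - 1 + g;
          if (ck < 0 || ck >= ncz) continue;
          double w = wx[a] * wy[b] * wz[g];
          if (w < 1e-8) continue;
          sup[ci + (R_xlen_t)ncx * (cj + (R_xlen_t)ncy * ck)]
              .push_back(std::make_pair(s, (float)w));
        }
      }
    }
  }

  Hist h(nbins);
  double sse = 0.0;
  if (metric == 0) {
    for (int s = 0; s < n; s++)
      h.add(fixedBins[s], mpos_of(mval[s], mmin, mrange, nbins), 1.0);
  } else {
    for (int s = 0; s < n; s++) {
      double d = mval[s] - fixedVals[s];
      sse += d * d;
    }
  }
  double be = bend.total();
  double data_cur = (metric == 0) ? h.nmi() : -sse / n;
  double cur = data_cur - lambda * be;
  double init = cur;
  const double eps = 1e-9;
  std::vector<double> newvals, Hbak, trial(n);

  // data-term gain of moving control cidx component d by delta, evaluated
  // incrementally over the control's support; histogram/state restored
  // unless `commit`
  auto probe = [&](R_xlen_t cidx, int d, double delta, bool commit) {
    const std::vector<std::pair<int, float> > &S = sup[cidx];
    double out;
    if (metric == 0) {
      Hbak = h.H;
      double tbak = h.total;
      newvals.resize(S.size());
      for (size_t q = 0; q < S.size(); q++) {
        int s = S[q].first;
        double w = S[q].second;
        h.add(fixedBins[s], mpos_of(mval[s], mmin, mrange, nbins), -1.0);
        double yy[3] = { bx[s] + ux[s], by[s] + uy[s], bz[s] + uz[s] };
        yy[d] += w * delta;
        newvals[q] = m.linear(yy[0], yy[1], yy[2], fill);
        h.add(fixedBins[s], mpos_of(newvals[q], mmin, mrange, nbins), 1.0);
      }
      out = h.nmi() - data_cur;
      if (!commit) { h.H = Hbak; h.total = tbak; }
    } else {
      double dsse = 0.0;
      newvals.resize(S.size());
      for (size_t q = 0; q < S.size(); q++) {
        int s = S[q].first;
        double w = S[q].second;
        double yy[3] = { bx[s] + ux[s], by[s] + uy[s], bz[s] + uz[s] };
        yy[d] += w * delta;
        newvals[q] = m.linear(yy[0], yy[1], yy[2], fill);
        double dn = newvals[q] - fixedVals[s], dold = mval[s] - fixedVals[s];
        dsse += dn * dn - dold * dold;
      }
      if (commit) sse += dsse;
      out = -dsse / n;
    }
    if (commit) {
      for (size_t q = 0; q < S.size(); q++) {
        int s = S[q].first;
        double w = S[q].second;
        if (d == 0) ux[s] += w * delta;
        else if (d == 1) uy[s] += w * delta;
        else uz[s] += w * delta;
        mval[s] = newvals[q];
      }
      C[cidx + nctrl * d] += delta;
    }
    return out;
  };

  auto ctrl_ijk = [&](R_xlen_t cidx, int *i, int *j, int *k) {
    *i = (int)(cidx % ncx);
    *j = (int)((cidx / ncx) % ncy);
    *k = (int)(cidx / ((R_xlen_t)ncx * ncy));
  };

  for (int si = 0; si < steps.size(); si++) {
    double step = steps[si];

    // phase 1: synchronized gradient-ascent moves. The analytic gradient of
    // the Parzen-binned metric w.r.t. every control coefficient is exact and
    // deterministic, so the collective ascent direction is found even where
    // any finite single-control move worsens the metric.
    for (int spass = 0; spass < sync_passes; spass++) {
      // per-sample d(metric)/d(moving value)
      std::vector<double> gs(n, 0.0);
      if (metric == 0) {
        double T = h.total;
        std::vector<double> pm(nbins, 0.0);
        double Hf = 0, Hm = 0, Hfm = 0;
        {
          std::vector<double> pf(nbins, 0.0);
          for (int i = 0; i < nbins; i++)
            for (int j = 0; j < nbins; j++) {
              double v = h.H[(size_t)i * nbins + j];
              pf[i] += v; pm[j] += v;
            }
          for (int i = 0; i < nbins; i++) {
            if (pf[i] > 0) { double p = pf[i] / T; Hf -= p * std::log(p); }
            if (pm[i] > 0) { double p = pm[i] / T; Hm -= p * std::log(p); }
          }
          for (size_t q2 = 0; q2 < h.H.size(); q2++)
            if (h.H[q2] > 0) { double p = h.H[q2] / T; Hfm -= p * std::log(p); }
        }
        if (Hfm <= 1e-12) break;
        const double tiny = 1e-12;
        for (int s = 0; s < n; s++) {
          double v = mpos_of(mval[s], mmin, mrange, nbins);
          int b0 = (int)std::floor(v);
          if (b0 >= nbins - 1) b0 = nbins - 2;
          if (b0 < 0) b0 = 0;
          int fb = fixedBins[s];
          // dNMI/dH_ij with the fixed marginal unchanged along this move
          auto dNMI_dH = [&](int j) {
            double pmj = std::max(pm[j] / T, tiny);
            double pij = std::max(h.H[(size_t)fb * nbins + j] / T, tiny);
            double dHm = -(1.0 + std::log(pmj)) / T;
            double dHfm = -(1.0 + std::log(pij)) / T;
            return (dHm * Hfm - (Hf + Hm) * dHfm) / (Hfm * Hfm);
          };
          gs[s] = (dNMI_dH(b0 + 1) - dNMI_dH(b0)) * (nbins - 1) / mrange;
        }
      } else {
        for (int s = 0; s < n; s++)
          gs[s] = -2.0 * (mval[s] - fixedVals[s]) / n;
      }
      // chain through the moving-image spatial gradient and the b-spline
      // weights to get the gradient per control coefficient
      std::vector<double> grad(nctrl * 3, 0.0);
      {
        std::vector<double> mg(3 * (size_t)n);
        double gtmp[3];
        for (int s = 0; s < n; s++) {
          m.linear_grad(bx[s] + ux[s], by[s] + uy[s], bz[s] + uz[s], fill, gtmp);
          mg[3 * (size_t)s] = gtmp[0];
          mg[3 * (size_t)s + 1] = gtmp[1];
          mg[3 * (size_t)s + 2] = gtmp[2];
        }
        for (R_xlen_t cidx = 0; cidx < nctrl; cidx++) {
          const std::vector<std::pair<int, float> > &S = sup[cidx];
          if (S.empty()) continue;
          double g0 = 0, g1 = 0, g2 = 0;
          for (size_t q2 = 0; q2 < S.size(); q2++) {
            int s = S[q2].first;
            double w = S[q2].second * gs[s];
            g0 += w * mg[3 * (size_t)s];
            g1 += w * mg[3 * (size_t)s + 1];
            g2 += w * mg[3 * (size_t)s + 2];
          }
          grad[cidx] = axes[0] ? g0 : 0.0;
          grad[cidx + nctrl] = axes[1] ? g1 : 0.0;
          grad[cidx + nctrl * 2] = axes[2] ? g2 : 0.0;
        }
        // bending-energy gradient: lambda * d/dc of mean squared second
        // differences = lambda * 2/(3 nc) * (L^T L c) with L the second-
        // difference operator; computed by applying the stencil twice
        for (int d = 0; d < 3; d++) {
          for (R_xlen_t cidx = 0; cidx < nctrl; cidx++) {
            int ci, cj, ck;
            ctrl_ijk(cidx, &ci, &cj, &ck);
            double acc = 0;
            for (int ax = 0; ax < 3; ax++) {
              for (int off = -1; off <= 1; off++) {
                int ii = ci + (ax == 0 ? off : 0);
                int jj = cj + (ax == 1 ? off : 0);
                int kk = ck + (ax == 2 ? off : 0);
                if (ii < 0 || jj < 0 || kk < 0 || ii >= ncx || jj >= ncy ||
                    kk >= ncz)
                  continue;
                double c2;
                if (ax == 0)
                  c2 = bend.cat(ii + 1, jj, kk, d) - 2 * bend.cat(ii, jj, kk, d) +
                       bend.cat(ii - 1, jj, kk, d);
                else if (ax == 1)
                  c2 = bend.cat(ii, jj + 1, kk, d) - 2 * bend.cat(ii, jj, kk, d) +
                       bend.cat(ii, jj - 1, kk, d);
                else
                  c2 = bend.cat(ii, jj, kk + 1, d) - 2 * bend.cat(ii, jj, kk, d) +
                       bend.cat(ii, jj, kk - 1, d);
                acc += c2 * (off == 0 ? -2.0 : 1.0);
              }
            }
            grad[cidx + nctrl * d] -= lambda * 2.0 * acc / (3.0 * nctrl);
          }
        }
      }
      double gmax = 0;
      for (R_xlen_t q2 = 0; q2 < nctrl * 3; q2++)
        gmax = std::max(gmax, std::fabs(grad[q2]));
      if (gmax < 1e-15) break;
      // scale so the largest control move equals the current step size
      std::vector<double> dir(nctrl * 3);
      for (R_xlen_t q2 = 0; q2 < nctrl * 3; q2++)
        dir[q2] = grad[q2] / gmax * step;
      std::vector<double> dux(n, 0.0), duy(n, 0.0), duz(n, 0.0);
      for (R_xlen_t cidx = 0; cidx < nctrl; cidx++) {
        const std::vector<std::pair<int, float> > &S = sup[cidx];
        for (int d = 0; d < 3; d++) {
          double dd = dir[cidx + nctrl * d];
          if (dd == 0.0) continue;
          for (size_t q = 0; q < S.size(); q++) {
            int s = S[q].first;
            double w = S[q].second;
            if (d == 0) dux[s] += w * dd;
            else if (d == 1) duy[s] += w * dd;
            else duz[s] += w * dd;
          }
        }
      }
      double best_alpha = 0.0, best_val = cur;
      for (double alpha = 1.0; alpha > 0.02; alpha *= 0.5) {
        double datav;
        if (metric == 0) {
          Hist ht(nbins);
          for (int s = 0; s < n; s++) {
            double yy[3] = { bx[s] + ux[s] + alpha * dux[s],
                             by[s] + uy[s] + alpha * duy[s],
                             bz[s] + uz[s] + alpha * duz[s] };
            trial[s] = m.linear(yy[0], yy[1], yy[2], fill);
            ht.add(fixedBins[s], mpos_of(trial[s], mmin, mrange, nbins), 1.0);
          }
          datav = ht.nmi();
        } else {
          double ss = 0.0;
          for (int s = 0; s < n; s++) {
            double yy[3] = { bx[s] + ux[s] + alpha * dux[s],
                             by[s] + uy[s] + alpha * duy[s],
                             bz[s] + uz[s] + alpha * duz[s] };
            trial[s] = m.linear(yy[0], yy[1], yy[2], fill);
            double dd = trial[s] - fixedVals[s];
            ss += dd * dd;
          }
          datav = -ss / n;
        }
        // bending of the trial coefficients
        for (R_xlen_t q = 0; q < nctrl * 3; q++) C[q] += alpha * dir[q];
        double bev = bend.total();
        for (R_xlen_t q = 0; q < nctrl * 3; q++) C[q] -= alpha * dir[q];
        double val = datav - lambda * bev;
        if (val > best_val + eps) { best_val = val; best_alpha = alpha; break; }
      }
      if (best_alpha == 0.0) break;
      for (R_xlen_t q = 0; q < nctrl * 3; q++) C[q] += best_alpha * dir[q];
      for (int s = 0; s < n; s++) {
        ux[s] += best_alpha * dux[s];
        uy[s] += best_alpha * duy[s];
        uz[s] += best_alpha * duz[s];
        double yy[3] = { bx[s] + ux[s], by[s] + uy[s], bz[s] + uz[s] };
        mval[s] = m.linear(yy[0], yy[1], yy[2], fill);
      }
      if (metric == 0) {
        Hist hn(nbins);
        for (int s = 0; s < n; s++)
          hn.add(fixedBins[s], mpos_of(mval[s], mmin, mrange, nbins), 1.0);
        h.H = hn.H;
        h.total = hn.total;
        data_cur = h.nmi();
      } else {
        sse = 0.0;
        for (int s = 0; s < n; s++) {
          double dd = mval[s] - fixedVals[s];
          sse += dd * dd;
        }
        data_cur = -sse / n;
      }
      be = bend.total();
      cur = data_cur - lambda * be;
    }

    // phase 2: greedy per-control refinement
    for (int pass = 0; pass < passes; pass++) {
      int accepted = 0;
      for (R_xlen_t cidx = 0; cidx < nctrl; cidx++) {
        if (sup[cidx].empty()) continue;
        int ci, cj, ck;
        ctrl_ijk(cidx, &ci, &cj, &ck);
        for (int d = 0; d < 3; d++) {
          if (!axes[d]) continue;
          for (int sgn = 0; sgn < 2; sgn++) {
            double delta = sgn == 0 ? step : -step;
            double dbe = bend.delta(ci, cj, ck, d, delta);
            double gain = probe(cidx, d, delta, false) - lambda * dbe;
            if (gain > eps) {
              probe(cidx, d, delta, true);
              if (metric == 0) data_cur = h.nmi();
              else data_cur = -sse / n;
              be += dbe;
              cur = data_cur - lambda * be;
              accepted++;
              break;
            }
          }
        }
      }
      if (accepted == 0) break;
    }
  }
  return List::create(_["coef"] = coef, _["metric_initial"] = init,
                      _["metric_final"] = cur);
}


// Analytic gradient of the Parzen-binned NMI data term w.r.t. b-spline
// control coefficients (debug/validation export).
// [[Rcpp::export]]
NumericVector cpp_nmi_grad(IntegerVector fixedBins, NumericMatrix pts,
                           NumericVector moving, NumericVector mspacing,
                           NumericVector morigin, NumericMatrix A,
                           NumericVector t, NumericVector coef0,
                           NumericVector gorigin, NumericVector gspacing,
                           int nbins, double mmin, double mmax, double fill) {
  Grid m(moving, mspacing, morigin);
  Affine af(A, t);
  NumericVector coef = clone(coef0);
  IntegerVector cd = coef.attr("dim");
  int ncx = cd[0], ncy = cd[1], ncz = cd[2];
  FFD ffd(coef, gorigin, gspacing);
  int n = pts.nrow();
  double mrange = std::max(mmax - mmin, 1e-12);
  std::vector<double> mval(n), px(n), py(n), pz(n);
  double p[3], y[3], u[3];
  Hist h(nbins);
  for (int s = 0; s < n; s++) {
    p[0] = pts(s, 0); p[1] = pts(s, 1); p[2] = pts(s, 2);
    af.apply(p, y);
    ffd.disp(p[0], p[1], p[2], u);
    px[s] = y[0] + u[0]; py[s] = y[1] + u[1]; pz[s] = y[2] + u[2];
    mval[s] = m.linear(px[s], py[s], pz[s], fill);
    h.add(fixedBins[s], mpos_of(mval[s], mmin, mrange, nbins), 1.0);
  }
  double T = h.total;
  std::vector<double> pm(nbins, 0.0), pf(nbins, 0.0);
  double Hf = 0, Hm = 0, Hfm = 0;
  for (int i = 0; i < nbins; i++)
    for (int j = 0; j < nbins; j++) {
      double v = h.H[(size_t)i * nbins + j];
      pf[i] += v; pm[j] += v;
    }
  for (int i = 0; i < nbins; i++) {
    if (pf[i] > 0) { double pp = pf[i] / T; Hf -= pp * std::log(pp); }
    if (pm[i] > 0) { double pp = pm[i] / T; Hm -= pp * std::log(pp); }
  }
  for (size_t q2 = 0; q2 < h.H.size(); q2++)
    if (h.H[q2] > 0) { double pp = h.H[q2] / T; Hfm -= pp * std::log(pp); }
  const double tiny = 1e-12;
  R_xlen_t nctrl = (R_xlen_t)ncx * ncy * ncz;
  NumericVector grad(nctrl * 3);
  grad.attr("dim") = cd;
  double gtmp[3];
  for (int s = 0; s < n; s++) {
    double v = mpos_of(mval[s], mmin, mrange, nbins);
    int b0 = (int)std::floor(v);
    if (b0 >= nbins - 1) b0 = nbins - 2;
    if (b0 < 0) b0 = 0;
    int fb = fixedBins[s];
    auto dNMI_dH = [&](int j) {
      double pmj = std::max(pm[j] / T, tiny);
      double pij = std::max(h.H[(size_t)fb * nbins + j] / T, tiny);
      double dHm = -(1.0 + std::log(pmj)) / T;
      double dHfm = -(1.0 + std::log(pij)) / T;
      return (dHm * Hfm - (Hf + Hm) * dHfm) / (Hfm * Hfm);
    };
    double gs = (dNMI_dH(b0 + 1) - dNMI_dH(b0)) * (nbins - 1) / mrange;
    m.linear_grad(px[s], py[s], pz[s], fill, gtmp);
    // accumulate over this sample's 64 support controls
    double tx = (pts(s, 0) - gorigin[0]) / gspacing[0];
    double ty = (pts(s, 1) - gorigin[1]) / gspacing[1];
    double tz = (pts(s, 2) - gorigin[2]) / gspacing[2];
    int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
    double wx[4], wy[4], wz[4];
    bspline_w(tx - ix, wx); bspline_w(ty - iy, wy); bspline_w(tz - iz, wz);
    for (int a = 0; a < 4; a++) {
      int ci = ix - 1 + a;
      if (ci < 0 || ci >= ncx) continue;
      for (int b = 0; b < 4; b++) {
        int cj = iy - 1 + b;
        if (cj < 0 || cj >= ncy) continue;
        for (int g = 0; g < 4; g++) {
          int ck = iz - 1 + g;
          if (ck < 0 || ck >= ncz) continue;
          double w = wx[a] * wy[b] * wz[g];
          R_xlen_t cidx = ci + (R_xlen_t)ncx * (cj + (R_xlen_t)ncy * ck);
          for (int d = 0; d < 3; d++)
            grad[cidx + nctrl * d] += w * gs * gtmp[d];
        }
      }
    }
  }
  return grad;
}

// ---------------- squared Euclidean distance transform ---------------------

// Felzenszwalb & Huttenlocher 1-D lower envelope, applied separably with
// anisotropic spacing. Input: binary array (non-zero = foreground); output:
// squared distance in mm^2 to the nearest foreground voxel.
static void dt1d(std::vector<double> &f, std::vector<double> &out, double s) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  double s2 = s * s;
  for (int q = 1; q < n; q++) {
    double sq = f[q] + s2 * q * q;
    double sv = f[v[k]] + s2 * v[k] * v[k];
    double denom = 2.0 * s2 * (q - v[k]);
    double ss = (sq - sv) / denom;
    while (ss <= z[k]) {
      k--;
      sv = f[v[k]] + s2 * v[k] * v[k];
      denom = 2.0 * s2 * (q - v[k]);
      ss = (sq - sv) / denom;
    }
    k++;
    v[k] = q;
    z[k] = ss;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = s * (q - v[k]);
    out[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sq_edt(NumericVector mask, NumericVector spacing) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector out(ntot);
  out.attr("dim") = d;
  const double INF = 1e18;
  for (R_xlen_t s = 0; s < ntot; s++) out[s] = mask[s] != 0 ? 0.0 : INF;
  std::vector<double> f(std::max(nx, std::max(ny, nz))),
      g(std::max(nx, std::max(ny, nz)));
  // x pass
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      f.assign(nx, 0); g.assign(nx, 0);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, g, spacing[0]);
      for (int i = 0; i < nx; i++) out[base + i] = g[i];
    }
  // y pass
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      f.assign(ny, 0); g.assign(ny, 0);
      for (int j = 0; j < ny; j++)
        f[j] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, g, spacing[1]);
      for (int j = 0; j < ny; j++)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = g[j];
    }
  // z pass
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      f.assign(nz, 0); g.assign(nz, 0);
      for (int k = 0; k < nz; k++)
        f[k] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, g, spacing[2]);
      for (int k = 0; k < nz; k++)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = g[k];
    }
  return out;
}

// ---------------- separable Gaussian smoothing -----------------------------

static void gauss1d(std::vector<double> &buf, std::vector<double> &tmp,
                    const std::vector<double> &k) {
  int n = (int)buf.size(), r = ((int)k.size() - 1) / 2;
  for (int i = 0; i < n; i++) {
    double acc = 0;
    for (int j = -r; j <= r; j++) {
      int q = i + j;
      if (q < 0) q = -q - 1;              // reflect
      if (q >= n) q = 2 * n - 1 - q;
      acc += buf[q] * k[j + r];
    }
    tmp[i] = acc;
  }
  buf = tmp;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, NumericVector spacing,
                               NumericVector sigma_mm) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out = clone(vol);
  out.attr("dim") = d;
  for (int axis = 0; axis < 3; axis++) {
    double sig = sigma_mm[axis] / spacing[axis];   // sigma in voxels
    if (sig < 0.3) continue;
    int r = std::max(1, (int)std::ceil(3 * sig));
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int j = -r; j <= r; j++) {
      k[j + r] = std::exp(-0.5 * j * j / (sig * sig));
      ksum += k[j + r];
    }
    for (size_t j = 0; j < k.size(); j++) k[j] /= ksum;
    int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
    std::vector<double> buf(n), tmp(n);
    if (axis == 0) {
      for (int kk = 0; kk < nz; kk++)
        for (int j = 0; j < ny; j++) {
          R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * kk);
          for (int i = 0; i < nx; i++) buf[i] = out[base + i];
          gauss1d(buf, tmp, k);
          for (int i = 0; i < nx; i++) out[base + i] = buf[i];
        }
    } else if (axis == 1) {
      for (int kk = 0; kk < nz; kk++)
        for (int i = 0; i < nx; i++) {
          for (int j = 0; j < ny; j++)
            buf[j] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * kk)];
          gauss1d(buf, tmp, k);
          for (int j = 0; j < ny; j++)
            out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * kk)] = buf[j];
        }
    } else {
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          for (int kk = 0; kk < nz; kk++)
            buf[kk] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * kk)];
          gauss1d(buf, tmp, k);
          for (int kk = 0; kk < nz; kk++)
            out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * kk)] = buf[kk];
        }
    }
  }
  return out;
}
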
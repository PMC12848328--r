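// Two-phase (liquid/gas) incompressible free-surface solver on a uniform
// staggered MAC grid over the vertical slice W1 x H_total.
//
//   * phase fraction r: cell centers, liquid = 1, gas = 0
//   * u: vertical faces (nx+1) x ny,  v: horizontal faces nx x (ny+1)
//   * VOF advection: Youngs-PLIC reconstruction with the conservative
//     dimensionally-split flux/dilation correction scheme (bounded for
//     CFL <= 0.5, conserves liquid volume to round-off for discretely
//     divergence-free velocity)
//   * surface tension: balanced-force CSF  F = sigma * kappa * grad(r),
//     kappa from smoothed-fraction face normals
//   * pressure-velocity coupling: PISO (explicit predictor + >=2
//     projection correctors), Jacobi-preconditioned conjugate gradients
//   * boundaries: no-slip bottom/side walls, fixed-pressure outlet on top
//   * agitation: non-inertial frame body force  -a w^2 sin(w t)  along x
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}
static inline double minmod(double a, double b) {
  if (a * b <= 0.0) return 0.0;
  return std::abs(a) < std::abs(b) ? a : b;
}

// ---------------------------------------------------------------------------
// PLIC geometry on the unit cell.  Liquid region {m1*x + m2*y <= alpha},
// m1, m2 >= 0 after mirroring, normalized so m1 + m2 = 1.
// ---------------------------------------------------------------------------

// Area of {m1 x + m2 y <= alpha} intersected with [x0,x1] x [0,1], m1,m2 >= 0.
static double strip_area_pos(double m1, double m2, double alpha,
                             double x0, double x1) {
  if (x1 <= x0) return 0.0;
  if (alpha <= 0.0) return 0.0;
  if (alpha >= m1 + m2) return x1 - x0;
  const double eps = 1e-12;
  if (m1 < eps && m2 < eps) return alpha > 0.0 ? (x1 - x0) : 0.0;
  if (m1 < eps) {                       // horizontal interface
    double c = clampd(alpha / m2, 0.0, 1.0);
    return c * (x1 - x0);
  }
  if (m2 < eps) {                       // vertical interface at x = alpha/m1
    double xc = alpha / m1;
    return clampd(xc, x0, x1) - x0;
  }
  // integrand clamp((alpha - m1 x)/m2, 0, 1): 1 below xa, 0 above xb
  double xa = (alpha - m2) / m1;
  double xb = alpha / m1;
  double a1 = clampd(xa, x0, x1);
  double b1 = clampd(xb, x0, x1);
  double area = (a1 - x0);              // fully liquid part
  if (b1 > a1) {
    area += (alpha * (b1 - a1) - 0.5 * m1 * (b1 * b1 - a1 * a1)) / m2;
  }
  return area;
}

// Area in vertical strip [x0,x1] for signed normal (m1, m2) with alpha given
// in the mirrored positive-normal frame (the frame alpha_from_fraction uses);
// a negative m1 mirrors the strip, a negative m2 leaves strip areas unchanged.
static double strip_area_signed(double m1, double m2, double alpha_pos,
                                double x0, double x1) {
  if (m1 < 0.0) {
    double nx0 = 1.0 - x1, nx1 = 1.0 - x0;
    x0 = nx0; x1 = nx1;
  }
  return strip_area_pos(std::abs(m1), std::abs(m2), alpha_pos, x0, x1);
}

// alpha (mirrored positive-normal frame) such that the liquid area over the
// whole unit cell equals frac.  Monotone bisection.
static double alpha_from_fraction(double m1, double m2, double frac) {
  double am1 = std::abs(m1), am2 = std::abs(m2);
  double lo = 0.0, hi = am1 + am2;
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    if (strip_area_pos(am1, am2, mid, 0.0, 1.0) < frac) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// ---------------------------------------------------------------------------
// Solver grid container
// ---------------------------------------------------------------------------
struct Grid {
  int nx, ny;
  double dx, dy;
  inline int C(int i, int j) const { return i + j * nx; }
  inline int U(int i, int j) const { return i + j * (nx + 1); }
  inline int V(int i, int j) const { return i + j * nx; }
};

// Youngs 3x3 gradient of r at cell (i,j); indices clamped or wrapped.
static void youngs_normal(const std::vector<double>& r, const Grid& g,
                          int i, int j, bool perx, bool pery,
                          double& m1, double& m2) {
  auto ix = [&](int ii) {
    if (perx) { ii %= g.nx; if (ii < 0) ii += g.nx; return ii; }
    return std::max(0, std::min(g.nx - 1, ii));
  };
  auto iy = [&](int jj) {
    if (pery) { jj %= g.ny; if (jj < 0) jj += g.ny; return jj; }
    return std::max(0, std::min(g.ny - 1, jj));
  };
  int W = ix(i - 1), E = ix(i + 1), S = iy(j - 1), N = iy(j + 1), jc = iy(j);
  int ic = ix(i);
  double gx = ((r[g.C(E, N)] + 2.0 * r[g.C(E, jc)] + r[g.C(E, S)]) -
               (r[g.C(W, N)] + 2.0 * r[g.C(W, jc)] + r[g.C(W, S)])) / 8.0;
  double gy = ((r[g.C(E, N)] + 2.0 * r[g.C(ic, N)] + r[g.C(W, N)]) -
               (r[g.C(E, S)] + 2.0 * r[g.C(ic, S)] + r[g.C(W, S)])) / 8.0;
  // normal points out of the liquid: m = -grad(r) in cell units
  m1 = -gx; m2 = -gy;
  double n1 = std::abs(m1) + std::abs(m2);
  if (n1 < 1e-12) { m1 = 0.0; m2 = 0.0; return; }
  m1 /= n1; m2 /= n1;
}

// ---------------------------------------------------------------------------
// VOF advection: one full step (x sweep + y sweep, order by parity), with
// the per-cell dilation correction (cc fixed at the start of the step).
// Returns clipped mass (cell fractions clipped outside [0,1]).
// ---------------------------------------------------------------------------
static double vof_advect(std::vector<double>& r, const std::vector<double>& u,
                         const std::vector<double>& v, const Grid& g,
                         double dt, bool perx, bool pery, bool x_first) {
  const int nx = g.nx, ny = g.ny;
  std::vector<double> cc(nx * ny);
  for (int k = 0; k < nx * ny; ++k) cc[k] = r[k] >= 0.5 ? 1.0 : 0.0;

  auto sweep_x = [&](std::vector<double>& rr) {
    std::vector<double> G((nx + 1) * ny, 0.0);
    for (int j = 0; j < ny; ++j) {
      for (int i = (perx ? 0 : 1); i <= (perx ? nx : nx - 1); ++i) {
        double uf = u[g.U(i, j)];
        if (uf == 0.0) continue;
        double delta = std::abs(uf) * dt / g.dx;
        int di = uf > 0.0 ? i - 1 : i;  // donor cell x-index
        if (perx) { di %= nx; if (di < 0) di += nx; }
        else if (di < 0 || di > nx - 1) continue; // inflow from outside: gas
        double rd = rr[g.C(di, j)];
        double fa;
        if (rd > 1.0 - 1e-9) fa = delta;
        else if (rd < 1e-9) fa = 0.0;
        else {
          double m1, m2;
          youngs_normal(rr, g, di, j, perx, pery, m1, m2);
          if (m1 == 0.0 && m2 == 0.0) fa = rd * delta;
          else {
            double alpha = alpha_from_fraction(m1, m2, rd);
            fa = uf > 0.0 ? strip_area_signed(m1, m2, alpha, 1.0 - delta, 1.0)
                          : strip_area_signed(m1, m2, alpha, 0.0, delta);
          }
        }
        G[g.U(i, j)] = (uf > 0.0 ? fa : -fa);
      }
    }
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int ip = i + 1;
        double div = (u[g.U(ip, j)] - u[g.U(i, j)]) / g.dx;
        rr[g.C(i, j)] += -(G[g.U(ip, j)] - G[g.U(i, j)]) +
                         cc[g.C(i, j)] * dt * div;
      }
  };

  auto sweep_y = [&](std::vector<double>& rr) {
    std::vector<double> H(nx * (ny + 1), 0.0);
    for (int j = (pery ? 0 : 1); j <= ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if (!pery && j == 0) continue;
        double vf = v[g.V(i, j)];
        if (vf == 0.0) continue;
        double delta = std::abs(vf) * dt / g.dy;
        int dj = vf > 0.0 ? j - 1 : j;
        if (pery) { dj %= ny; if (dj < 0) dj += ny; }
        else if (dj < 0 || dj > ny - 1) continue; // above top: gas inflow
        double rd = rr[g.C(i, dj)];
        double fa;
        if (rd > 1.0 - 1e-9) fa = delta;
        else if (rd < 1e-9) fa = 0.0;
        else {
          double m1, m2;
          youngs_normal(rr, g, i, dj, perx, pery, m1, m2);
          if (m1 == 0.0 && m2 == 0.0) fa = rd * delta;
          else {
            double alpha = alpha_from_fraction(m1, m2, rd);
            // strip in y: swap axes (alpha is axis-swap invariant)
            fa = vf > 0.0 ? strip_area_signed(m2, m1, alpha, 1.0 - delta, 1.0)
                          : strip_area_signed(m2, m1, alpha, 0.0, delta);
          }
        }
        H[g.V(i, j)] = (vf > 0.0 ? fa : -fa);
      }
    }
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double div = (v[g.V(i, j + 1)] - v[g.V(i, j)]) / g.dy;
        rr[g.C(i, j)] += -(H[g.V(i, j + 1)] - H[g.V(i, j)]) +
                         cc[g.C(i, j)] * dt * div;
      }
  };

  if (x_first) { sweep_x(r); sweep_y(r); } else { sweep_y(r); sweep_x(r); }

  double clipped = 0.0;
  for (int k = 0; k < nx * ny; ++k) {
    if (r[k] < 0.0) { clipped += -r[k]; r[k] = 0.0; }
    else if (r[k] > 1.0) { clipped += r[k] - 1.0; r[k] = 1.0; }
  }
  return clipped;
}

// ---------------------------------------------------------------------------
// Smoothing (9-point kernel applied n_pass times, clamped at boundaries)
// ---------------------------------------------------------------------------
static void smooth_field(const std::vector<double>& src,
                         std::vector<double>& dst, const Grid& g,
                         int n_pass) {
  const int nx = g.nx, ny = g.ny;
  std::vector<double> a(src), b(nx * ny);
  for (int pass = 0; pass < n_pass; ++pass) {
    for (int j = 0; j < ny; ++j) {
      int jm = std::max(0, j - 1), jp = std::min(ny - 1, j + 1);
      for (int i = 0; i < nx; ++i) {
        int im = std::max(0, i - 1), ip = std::min(nx - 1, i + 1);
        b[g.C(i, j)] = (a[g.C(im, jm)] + 2.0 * a[g.C(i, jm)] + a[g.C(ip, jm)] +
                        2.0 * a[g.C(im, j)] + 4.0 * a[g.C(i, j)] +
                        2.0 * a[g.C(ip, j)] +
                        a[g.C(im, jp)] + 2.0 * a[g.C(i, jp)] +
                        a[g.C(ip, jp)]) / 16.0;
      }
    }
    std::swap(a, b);
  }
  dst = a;
}

// ---------------------------------------------------------------------------
// Interface curvature from smoothed fraction; kappa = -div(n_face),
// zeroed where the (unsmoothed) cell gradient is negligible.
// ---------------------------------------------------------------------------
static void curvature_fields(const std::vector<double>& r, const Grid& g,
                             int smooth_passes,
                             std::vector<double>& kappa,
                             std::vector<double>& wgrad) {
  const int nx = g.nx, ny = g.ny;
  const double dx = g.dx, dy = g.dy;
  std::vector<double> rs;
  smooth_field(r, rs, g, smooth_passes);

  std::vector<double> nxf((nx + 1) * ny, 0.0), nyf(nx * (ny + 1), 0.0);
  for (int j = 0; j < ny; ++j) {
    int jm = std::max(0, j - 1), jp = std::min(ny - 1, j + 1);
    double denY = (jp - jm) * dy;
    for (int i = 1; i < nx; ++i) {
      double gx = (rs[g.C(i, j)] - rs[g.C(i - 1, j)]) / dx;
      double gy = 0.5 * ((rs[g.C(i - 1, jp)] - rs[g.C(i - 1, jm)]) +
                         (rs[g.C(i, jp)] - rs[g.C(i, jm)])) / denY;
      double mag = std::sqrt(gx * gx + gy * gy);
      if (mag > 1e-12) nxf[g.U(i, j)] = gx / mag;
    }
    // wall faces: copy adjacent interior face (zero-gradient)
    nxf[g.U(0, j)] = nxf[g.U(1, j)];
    nxf[g.U(nx, j)] = nxf[g.U(nx - 1, j)];
  }
  for (int j = 1; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int im = std::max(0, i - 1), ip = std::min(nx - 1, i + 1);
      double denX = (ip - im) * dx;
      double gy = (rs[g.C(i, j)] - rs[g.C(i, j - 1)]) / dy;
      double gx = 0.5 * ((rs[g.C(ip, j - 1)] - rs[g.C(im, j - 1)]) +
                         (rs[g.C(ip, j)] - rs[g.C(im, j)])) / denX;
      double mag = std::sqrt(gx * gx + gy * gy);
      if (mag > 1e-12) nyf[g.V(i, j)] = gy / mag;
    }
  }
  for (int i = 0; i < nx; ++i) {
    nyf[g.V(i, 0)] = nyf[g.V(i, 1)];
    nyf[g.V(i, ny)] = nyf[g.V(i, ny - 1)];
  }

  kappa.assign(nx * ny, 0.0);
  wgrad.assign(nx * ny, 0.0);
  const double hmin = std::min(dx, dy);
  const int HW = 3;                     // height-function column half-height
  auto clampi = [](int a, int lo, int hi) {
    return a < lo ? lo : (a > hi ? hi : a);
  };
  for (int j = 0; j < ny; ++j) {
    int jm = std::max(0, j - 1), jp = std::min(ny - 1, j + 1);
    for (int i = 0; i < nx; ++i) {
      int im = std::max(0, i - 1), ip = std::min(nx - 1, i + 1);
      double cgx = (r[g.C(ip, j)] - r[g.C(im, j)]) / ((ip - im) * dx);
      double cgy = (r[g.C(i, jp)] - r[g.C(i, jm)]) / ((jp - jm) * dy);
      double w = std::sqrt(cgx * cgx + cgy * cgy);
      wgrad[g.C(i, j)] = w;
      if (w * hmin < 5e-3) continue;   // not an interface cell

      // height-function curvature: liquid thickness H in the three
      // columns normal to the dominant interface direction;
      // kappa = -H'' / (1 + H'^2)^(3/2) for either phase arrangement
      double gx_s = (rs[g.C(ip, j)] - rs[g.C(im, j)]) / ((ip - im) * dx);
      double gy_s = (rs[g.C(i, jp)] - rs[g.C(i, jm)]) / ((jp - jm) * dy);
      bool vertical = std::abs(gy_s) >= std::abs(gx_s);
      bool ok = true;
      double H[3];
      if (vertical) {
        for (int c = -1; c <= 1 && ok; ++c) {
          int ic = clampi(i + c, 0, nx - 1);
          double s = 0.0;
          for (int d = -HW; d <= HW; ++d)
            s += r[g.C(ic, clampi(j + d, 0, ny - 1))];
          // window must bracket the interface: pure cells at both ends
          double e0 = r[g.C(ic, clampi(j - HW, 0, ny - 1))];
          double e1 = r[g.C(ic, clampi(j + HW, 0, ny - 1))];
          bool pure_ends = (e0 > 0.99 && e1 < 0.01) ||
                           (e0 < 0.01 && e1 > 0.99);
          if (!pure_ends || s < 0.5 || s > 2 * HW + 0.5) ok = false;
          H[c + 1] = s * dy;
        }
        if (ok) {
          double h1 = (H[2] - H[0]) / (2.0 * dx);
          double h2 = (H[2] - 2.0 * H[1] + H[0]) / (dx * dx);
          kappa[g.C(i, j)] = -h2 / std::pow(1.0 + h1 * h1, 1.5);
          continue;
        }
      } else {
        for (int c = -1; c <= 1 && ok; ++c) {
          int jc = clampi(j + c, 0, ny - 1);
          double s = 0.0;
          for (int d = -HW; d <= HW; ++d)
            s += r[g.C(clampi(i + d, 0, nx - 1), jc)];
          double e0 = r[g.C(clampi(i - HW, 0, nx - 1), jc)];
          double e1 = r[g.C(clampi(i + HW, 0, nx - 1), jc)];
          bool pure_ends = (e0 > 0.99 && e1 < 0.01) ||
                           (e0 < 0.01 && e1 > 0.99);
          if (!pure_ends || s < 0.5 || s > 2 * HW + 0.5) ok = false;
          H[c + 1] = s * dx;
        }
        if (ok) {
          double h1 = (H[2] - H[0]) / (2.0 * dy);
          double h2 = (H[2] - 2.0 * H[1] + H[0]) / (dy * dy);
          kappa[g.C(i, j)] = -h2 / std::pow(1.0 + h1 * h1, 1.5);
          continue;
        }
      }
      // fallback: divergence of the smoothed-fraction face normals
      kappa[g.C(i, j)] =
        -((nxf[g.U(i + 1, j)] - nxf[g.U(i, j)]) / dx +
          (nyf[g.V(i, j + 1)] - nyf[g.V(i, j)]) / dy);
    }
  }
}

// ---------------------------------------------------------------------------
// Marching squares on a wall-padded cell-centered fraction field.
// Returns interface length (m) and the contour-length-weighted mean speed.
// ---------------------------------------------------------------------------
struct IfaceResult { double length; double v_interface; int n_segments; };

static IfaceResult marching_interface(const std::vector<double>& r,
                                      const std::vector<double>& uc,
                                      const std::vector<double>& vc,
                                      const Grid& g) {
  const int nx = g.nx, ny = g.ny;
  const int px = nx + 2, py = ny + 2;
  std::vector<double> R(px * py), UC(px * py), VC(px * py), X(px), Y(py);
  auto P = [&](int i, int j) { return i + j * px; };
  for (int j = 0; j < py; ++j) {
    int jj = std::max(0, std::min(ny - 1, j - 1));
    for (int i = 0; i < px; ++i) {
      int ii = std::max(0, std::min(nx - 1, i - 1));
      R[P(i, j)] = r[g.C(ii, jj)];
      UC[P(i, j)] = uc[g.C(ii, jj)];
      VC[P(i, j)] = vc[g.C(ii, jj)];
    }
  }
  X[0] = 0.0; X[px - 1] = nx * g.dx;
  for (int i = 1; i < px - 1; ++i) X[i] = (i - 0.5) * g.dx;
  Y[0] = 0.0; Y[py - 1] = ny * g.dy;
  for (int j = 1; j < py - 1; ++j) Y[j] = (j - 0.5) * g.dy;

  const double iso = 0.5;
  double total_len = 0.0, wspeed = 0.0;
  int nseg = 0;

  // crossing point + interpolated speed along an edge between nodes a and b
  auto cross = [&](int ia, int ja, int ib, int jb, double& cx, double& cy,
                   double& cs) {
    double va = R[P(ia, ja)], vb = R[P(ib, jb)];
    double t = (iso - va) / (vb - va);
    t = clampd(t, 0.0, 1.0);
    cx = X[ia] + t * (X[ib] - X[ia]);
    cy = Y[ja] + t * (Y[jb] - Y[ja]);
    double ua = UC[P(ia, ja)], ub = UC[P(ib, jb)];
    double wa = VC[P(ia, ja)], wb = VC[P(ib, jb)];
    double uu = ua + t * (ub - ua), vv = wa + t * (wb - wa);
    cs = std::sqrt(uu * uu + vv * vv);
  };

  for (int j = 0; j < py - 1; ++j) {
    for (int i = 0; i < px - 1; ++i) {
      double v00 = R[P(i, j)], v10 = R[P(i + 1, j)];
      double v11 = R[P(i + 1, j + 1)], v01 = R[P(i, j + 1)];
      int code = (v00 >= iso) | ((v10 >= iso) << 1) |
                 ((v11 >= iso) << 2) | ((v01 >= iso) << 3);
      if (code == 0 || code == 15) continue;
      // edge crossings: 0 bottom, 1 right, 2 top, 3 left
      double ex[4], ey[4], es[4];
      bool has[4] = {false, false, false, false};
      if ((v00 >= iso) != (v10 >= iso)) { cross(i, j, i + 1, j, ex[0], ey[0], es[0]); has[0] = true; }
      if ((v10 >= iso) != (v11 >= iso)) { cross(i + 1, j, i + 1, j + 1, ex[1], ey[1], es[1]); has[1] = true; }
      if ((v01 >= iso) != (v11 >= iso)) { cross(i, j + 1, i + 1, j + 1, ex[2], ey[2], es[2]); has[2] = true; }
      if ((v00 >= iso) != (v01 >= iso)) { cross(i, j, i, j + 1, ex[3], ey[3], es[3]); has[3] = true; }
      int pairs[2][2]; int npair = 0;
      if (code == 5 || code == 10) {
        // saddle: connect by the cell-center average
        double cen = 0.25 * (v00 + v10 + v11 + v01);
        bool center_in = cen >= iso;
        if ((code == 5) == center_in) {
          pairs[0][0] = 0; pairs[0][1] = 1; pairs[1][0] = 2; pairs[1][1] = 3;
        } else {
          pairs[0][0] = 0; pairs[0][1] = 3; pairs[1][0] = 1; pairs[1][1] = 2;
        }
        npair = 2;
      } else {
        int e[2], ne = 0;
        for (int k = 0; k < 4; ++k) if (has[k] && ne < 2) e[ne++] = k;
        if (ne == 2) { pairs[0][0] = e[0]; pairs[0][1] = e[1]; npair = 1; }
      }
      for (int k = 0; k < npair; ++k) {
        int ea = pairs[k][0], eb = pairs[k][1];
        if (!(has[ea] && has[eb])) continue;
        double ddx = ex[ea] - ex[eb], ddy = ey[ea] - ey[eb];
        double len = std::sqrt(ddx * ddx + ddy * ddy);
        if (len <= 0.0) continue;
        total_len += len;
        wspeed += 0.5 * (es[ea] + es[eb]) * len;
        nseg++;
      }
    }
  }
  IfaceResult out;
  out.length = total_len;
  out.v_interface = total_len > 0.0 ? wspeed / total_len : NA_REAL;
  out.n_segments = nseg;
  return out;
}

// ---------------------------------------------------------------------------
// Jacobi-preconditioned CG for the pressure-correction system
//   L(pc) = b,  L negative definite  ->  solve (-L) pc = -b
// Returns iterations used, or -1 on non-convergence.
// ---------------------------------------------------------------------------
struct PoissonCoef {
  std::vector<double> aE, aW, aN, aS, diag; // of (-L), diag > 0
  std::vector<double> ic_d;                 // IC(0) pivot diagonal
};

// Incomplete Cholesky (zero fill) pivots for the 5-point SPD system
//   M = (D + Ls) Dic^{-1} (D + Ls)^T  with Ls the strict lower triangle.
static void ic0_factor(PoissonCoef& A, const Grid& g) {
  const int nx = g.nx, ny = g.ny;
  A.ic_d.assign(nx * ny, 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int k = g.C(i, j);
      double d = A.diag[k];
      if (i > 0) { double a = A.aW[k]; d -= a * a / A.ic_d[g.C(i - 1, j)]; }
      if (j > 0) { double a = A.aS[k]; d -= a * a / A.ic_d[g.C(i, j - 1)]; }
      if (d < 1e-30) d = A.diag[k];     // breakdown guard
      A.ic_d[k] = d;
    }
}

static int pcg_solve(const PoissonCoef& A, const Grid& g,
                     const std::vector<double>& b, std::vector<double>& x,
                     double rtol, int maxit, double& final_res,
                     bool warm_start) {
  const int n = g.nx * g.ny;
  const int nx = g.nx, ny = g.ny;
  std::vector<double> rr(n), z(n), pdir(n), Ap(n);
  if (!warm_start) std::fill(x.begin(), x.end(), 0.0);
  double bnorm = 0.0;
  for (int k = 0; k < n; ++k) bnorm += b[k] * b[k];
  bnorm = std::sqrt(bnorm);
  final_res = bnorm;
  if (bnorm < 1e-300) { std::fill(x.begin(), x.end(), 0.0); return 0; }
  double target = rtol * bnorm;

  auto applyA = [&](const std::vector<double>& in, std::vector<double>& out) {
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int k = g.C(i, j);
        double s = A.diag[k] * in[k];
        if (i > 0)       s -= A.aW[k] * in[g.C(i - 1, j)];
        if (i < nx - 1)  s -= A.aE[k] * in[g.C(i + 1, j)];
        if (j > 0)       s -= A.aS[k] * in[g.C(i, j - 1)];
        if (j < ny - 1)  s -= A.aN[k] * in[g.C(i, j + 1)];
        out[k] = s;
      }
  };

  // IC(0) preconditioner application  z = M^{-1} rr
  auto applyM = [&](const std::vector<double>& in, std::vector<double>& out) {
    // forward: (D + Ls) y = in   (strict lower entries are -aW, -aS)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int k = g.C(i, j);
        double s = in[k];
        if (i > 0) s += A.aW[k] * out[g.C(i - 1, j)];
        if (j > 0) s += A.aS[k] * out[g.C(i, j - 1)];
        out[k] = s / A.ic_d[k];
      }
    // scale: z <- Dic y, then backward (D + Ls^T) z = .
    for (int k = 0; k < n; ++k) out[k] *= A.ic_d[k];
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        int k = g.C(i, j);
        double s = out[k];
        if (i < nx - 1) s += A.aE[k] * out[g.C(i + 1, j)];
        if (j < ny - 1) s += A.aN[k] * out[g.C(i, j + 1)];
        out[k] = s / A.ic_d[k];
      }
  };

  // initial residual rr = -b - A x0
  applyA(x, Ap);
  double r0n = 0.0;
  for (int k = 0; k < n; ++k) { rr[k] = -b[k] - Ap[k]; r0n += rr[k] * rr[k]; }
  final_res = std::sqrt(r0n);
  if (final_res <= target) return 0;

  applyM(rr, z);
  double rz = 0.0;
  for (int k = 0; k < n; ++k) rz += rr[k] * z[k];
  pdir = z;
  for (int it = 1; it <= maxit; ++it) {
    applyA(pdir, Ap);
    double pAp = 0.0;
    for (int k = 0; k < n; ++k) pAp += pdir[k] * Ap[k];
    if (pAp <= 0.0) break;
    double alpha = rz / pAp;
    double rnorm = 0.0;
    for (int k = 0; k < n; ++k) {
      x[k] += alpha * pdir[k];
      rr[k] -= alpha * Ap[k];
      rnorm += rr[k] * rr[k];
    }
    rnorm = std::sqrt(rnorm);
    final_res = rnorm;
    if (rnorm <= target) return it;
    applyM(rr, z);
    double rz_new = 0.0;
    for (int k = 0; k < n; ++k) rz_new += rr[k] * z[k];
    double beta = rz_new / rz;
    rz = rz_new;
    for (int k = 0; k < n; ++k) pdir[k] = z[k] + beta * pdir[k];
  }
  return -1;
}

// ===========================================================================
// Exported kernels (unit-testable pieces)
// ===========================================================================

// [[Rcpp::export(name = ".advect_vof_cpp")]]
List advect_vof_cpp(NumericMatrix r, NumericMatrix u, NumericMatrix v,
                    double dx, double dy, double dt,
                    bool periodic_x = false, bool periodic_y = false,
                    bool x_first = true) {
  Grid g; g.nx = r.nrow(); g.ny = r.ncol(); g.dx = dx; g.dy = dy;
  if (u.nrow() != g.nx + 1 || u.ncol() != g.ny)
    stop("u must be (nx+1) x ny");
  if (v.nrow() != g.nx || v.ncol() != g.ny + 1)
    stop("v must be nx x (ny+1)");
  // CFL check
  double cmax = 0.0;
  for (int k = 0; k < u.size(); ++k) cmax = std::max(cmax, std::abs(u[k]) * dt / dx);
  for (int k = 0; k < v.size(); ++k) cmax = std::max(cmax, std::abs(v[k]) * dt / dy);
  if (cmax > 0.5 + 1e-12)
    stop("CFL violation in VOF advection: max |c| dt/h = %f > 0.5", cmax);
  std::vector<double> rv(r.begin(), r.end());
  std::vector<double> uv(u.begin(), u.end()), vv(v.begin(), v.end());
  double clipped = vof_advect(rv, uv, vv, g, dt, periodic_x, periodic_y, x_first);
  NumericMatrix out(g.nx, g.ny);
  std::copy(rv.begin(), rv.end(), out.begin());
  return List::create(_["r"] = out, _["clipped"] = clipped);
}

// [[Rcpp::export(name = ".curvature_cpp")]]
List curvature_cpp(NumericMatrix r, double dx, double dy,
                   int smooth_passes = 2) {
  Grid g; g.nx = r.nrow(); g.ny = r.ncol(); g.dx = dx; g.dy = dy;
  std::vector<double> rv(r.begin(), r.end()), kappa, w;
  curvature_fields(rv, g, smooth_passes, kappa, w);
  NumericMatrix K(g.nx, g.ny), W(g.nx, g.ny);
  std::copy(kappa.begin(), kappa.end(), K.begin());
  std::copy(w.begin(), w.end(), W.begin());
  return List::create(_["kappa"] = K, _["grad_mag"] = W);
}

// [[Rcpp::export(name = ".interface_geometry_cpp")]]
List interface_geometry_cpp(NumericMatrix r, NumericMatrix uc,
                            NumericMatrix vc, double dx, double dy) {
  Grid g; g.nx = r.nrow(); g.ny = r.ncol(); g.dx = dx; g.dy = dy;
  std::vector<double> rv(r.begin(), r.end());
  std::vector<double> ucv(uc.begin(), uc.end()), vcv(vc.begin(), vc.end());
  IfaceResult res = marching_interface(rv, ucv, vcv, g);
  return List::create(_["length"] = res.length,
                      _["v_interface"] = res.v_interface,
                      _["n_segments"] = res.n_segments);
}

// ===========================================================================
// Full transient run
// ===========================================================================

// [[Rcpp::export(name = ".vof_run_cpp")]]
List vof_run_cpp(NumericMatrix r0, NumericMatrix u0, NumericMatrix v0,
                 NumericMatrix p0,
                 double dx, double dy,
                 double rho_l, double mu_l, double rho_g, double mu_g,
                 double sigma, double gravity,
                 double amp, double omega,
                 double t0, double t_end,
                 double cfl, double capillary_safety, int n_correctors,
                 double poisson_tol, int max_poisson_iter,
                 double dt_max, int diag_every,
                 NumericVector snapshot_times,
                 int max_steps = 2000000,
                 int curvature_smoothing = 2) {
  Grid g; g.nx = r0.nrow(); g.ny = r0.ncol(); g.dx = dx; g.dy = dy;
  const int nx = g.nx, ny = g.ny;
  if (u0.nrow() != nx + 1 || u0.ncol() != ny) stop("u0 must be (nx+1) x ny");
  if (v0.nrow() != nx || v0.ncol() != ny + 1) stop("v0 must be nx x (ny+1)");
  if (p0.nrow() != nx || p0.ncol() != ny) stop("p0 must be nx x ny");

  std::vector<double> r(r0.begin(), r0.end());
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> p(p0.begin(), p0.end());

  std::vector<double> rho_c(nx * ny), mu_c(nx * ny);
  std::vector<double> kappa, wgrad;
  std::vector<double> us((nx + 1) * ny), vs(nx * (ny + 1));
  std::vector<double> b(nx * ny), pc(nx * ny);
  PoissonCoef A;
  A.aE.resize(nx * ny); A.aW.resize(nx * ny);
  A.aN.resize(nx * ny); A.aS.resize(nx * ny); A.diag.resize(nx * ny);

  // diagnostics rows
  std::vector<double> diag_rows;
  const int NDIAG = 15;
  auto push_diag = [&](double t, double dt, int cg_iters, double div_max,
                       double clipped) {
    // cell-centered velocity
    double sum_rw = 0.0, sum_r = 0.0, max_liq = 0.0, vol = 0.0, cx = 0.0;
    std::vector<double> uc(nx * ny), vc(nx * ny);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int k = g.C(i, j);
        uc[k] = 0.5 * (u[g.U(i, j)] + u[g.U(i + 1, j)]);
        vc[k] = 0.5 * (v[g.V(i, j)] + v[g.V(i, j + 1)]);
        double sp = std::sqrt(uc[k] * uc[k] + vc[k] * vc[k]);
        sum_rw += r[k] * sp;
        sum_r += r[k];
        vol += r[k];
        cx += r[k] * (i + 0.5) * dx;
        if (r[k] > 0.5 && sp > max_liq) max_liq = sp;
      }
    double vavg = sum_r > 0.0 ? sum_rw / sum_r : 0.0;
    cx = sum_r > 0.0 ? cx / sum_r : NA_REAL;
    vol *= dx * dy;

    // wall shear stress over wetted faces (bottom + sides), one-sided
    double wss_sum = 0.0, wss_len = 0.0, wss_max = 0.0;
    for (int i = 0; i < nx; ++i) {       // bottom wall
      int k = g.C(i, 0);
      if (r[k] <= 0.5) continue;
      double ut = 0.5 * (u[g.U(i, 0)] + u[g.U(i + 1, 0)]);
      double tau = mu_c[k] * std::abs(ut) / (0.5 * dy);
      wss_sum += tau * dx; wss_len += dx;
      if (tau > wss_max) wss_max = tau;
    }
    for (int j = 0; j < ny; ++j) {       // side walls
      int kl = g.C(0, j);
      if (r[kl] > 0.5) {
        double vt = 0.5 * (v[g.V(0, j)] + v[g.V(0, j + 1)]);
        double tau = mu_c[kl] * std::abs(vt) / (0.5 * dx);
        wss_sum += tau * dy; wss_len += dy;
        if (tau > wss_max) wss_max = tau;
      }
      int kr = g.C(nx - 1, j);
      if (r[kr] > 0.5) {
        double vt = 0.5 * (v[g.V(nx - 1, j)] + v[g.V(nx - 1, j + 1)]);
        double tau = mu_c[kr] * std::abs(vt) / (0.5 * dx);
        wss_sum += tau * dy; wss_len += dy;
        if (tau > wss_max) wss_max = tau;
      }
    }
    double wss_avg = wss_len > 0.0 ? wss_sum / wss_len : 0.0;

    IfaceResult ir = marching_interface(r, uc, vc, g);
    int mixed = 0;
    for (int k = 0; k < nx * ny; ++k)
      if (r[k] > 0.01 && r[k] < 0.99) mixed++;

    double row[NDIAG] = {t, dt, vavg, max_liq, wss_avg, wss_max,
                         ir.length, ir.v_interface, vol, div_max,
                         (double)cg_iters, clipped, (double)mixed,
                         (double)ir.n_segments, cx};
    diag_rows.insert(diag_rows.end(), row, row + NDIAG);
  };

  // snapshots
  std::vector<double> snaps(snapshot_times.begin(), snapshot_times.end());
  std::sort(snaps.begin(), snaps.end());
  size_t snap_idx = 0;
  while (snap_idx < snaps.size() && snaps[snap_idx] <= t0 + 1e-12) snap_idx++;
  List snapshots;

  auto store_snapshot = [&](double t) {
    NumericMatrix R(nx, ny), U(nx + 1, ny), V(nx, ny + 1), P(nx, ny);
    std::copy(r.begin(), r.end(), R.begin());
    std::copy(u.begin(), u.end(), U.begin());
    std::copy(v.begin(), v.end(), V.begin());
    std::copy(p.begin(), p.end(), P.begin());
    snapshots.push_back(List::create(_["t"] = t, _["r"] = R, _["u"] = U,
                                     _["v"] = V, _["p"] = P));
  };

  const double rho_mean = 0.5 * (rho_l + rho_g);
  const double hmin = std::min(dx, dy);
  const double dt_cap = sigma > 0.0
    ? std::sqrt(rho_mean * hmin * hmin * hmin / (2.0 * M_PI * sigma))
    : R_PosInf;
  const double dt_visc = 0.25 * hmin * hmin *
    std::min(rho_l / mu_l, rho_g / mu_g);

  double t = t0;
  int step = 0;
  std::string status = "ok";
  double last_res = 0.0;
  bool x_first = true;

  // mixture properties for initial diagnostics
  for (int k = 0; k < nx * ny; ++k) {
    rho_c[k] = r[k] * rho_l + (1.0 - r[k]) * rho_g;
    mu_c[k] = r[k] * mu_l + (1.0 - r[k]) * mu_g;
  }
  push_diag(t, 0.0, 0, 0.0, 0.0);

  while (t < t_end - 1e-12) {
    if (++step > max_steps) { status = "max_steps_exceeded"; break; }

    // --- mixture properties
    for (int k = 0; k < nx * ny; ++k) {
      rho_c[k] = r[k] * rho_l + (1.0 - r[k]) * rho_g;
      mu_c[k] = r[k] * mu_l + (1.0 - r[k]) * mu_g;
    }

    // --- timestep
    double umax = 0.0, vmax = 0.0;
    for (size_t k = 0; k < u.size(); ++k) umax = std::max(umax, std::abs(u[k]));
    for (size_t k = 0; k < v.size(); ++k) vmax = std::max(vmax, std::abs(v[k]));
    double vel_scale = std::max(std::max(umax, vmax), amp * omega);
    double dt_cfl = vel_scale > 0.0
      ? cfl * hmin / vel_scale : R_PosInf;
    double dt = capillary_safety * std::min(dt_cfl, std::min(dt_cap, dt_visc));
    if (dt > dt_max) dt = dt_max;
    if (t + dt > t_end) dt = t_end - t;
    if (snap_idx < snaps.size() && t + dt > snaps[snap_idx] - 1e-12)
      dt = snaps[snap_idx] - t;
    if (dt <= 0.0) { status = "nonpositive_dt"; break; }

    double accx = -amp * omega * omega * std::sin(omega * (t + dt));

    // --- curvature + CSF weights
    curvature_fields(r, g, curvature_smoothing, kappa, wgrad);

    // --- predictor
    auto ughost = [&](int i, int j) -> double {
      if (j < 0) return -u[g.U(i, 0)];
      if (j > ny - 1) return u[g.U(i, ny - 1)];
      return u[g.U(i, j)];
    };
    auto vghost = [&](int i, int j) -> double {
      if (j > ny) j = ny;              // zero-gradient above the outlet
      if (i < 0) return -v[g.V(0, j)];
      if (i > nx - 1) return -v[g.V(nx - 1, j)];
      return v[g.V(i, j)];
    };
    auto mu_corner = [&](int i, int j) -> double {
      // corner at (x_i, y_j) of the cell grid: average adjacent cells
      int il = std::max(0, i - 1), ir_ = std::min(nx - 1, i);
      int jb = std::max(0, j - 1), jt = std::min(ny - 1, j);
      return 0.25 * (mu_c[g.C(il, jb)] + mu_c[g.C(ir_, jb)] +
                     mu_c[g.C(il, jt)] + mu_c[g.C(ir_, jt)]);
    };

    // u predictor (interior x-faces)
    for (int j = 0; j < ny; ++j) {
      for (int i = 1; i < nx; ++i) {
        double rhoF = 0.5 * (rho_c[g.C(i - 1, j)] + rho_c[g.C(i, j)]);
        double ucen = u[g.U(i, j)];
        // d(u)/dx with MUSCL face values (u nodes spaced dx along x)
        double dm1 = (i >= 2) ? u[g.U(i, j)] - u[g.U(i - 1, j)] : 0.0;
        double dm2 = (i >= 3) ? u[g.U(i - 1, j)] - u[g.U(i - 2, j)] : 0.0;
        double dp1 = (i <= nx - 2) ? u[g.U(i + 1, j)] - u[g.U(i, j)] : 0.0;
        double dp2 = (i <= nx - 3) ? u[g.U(i + 2, j)] - u[g.U(i + 1, j)] : 0.0;
        double fR, fL;
        if (ucen > 0.0) {
          fR = u[g.U(i, j)] + 0.5 * minmod(dp1, dm1);
          fL = (i >= 1 ? u[g.U(i - 1, j)] : 0.0) + 0.5 * minmod(dm1, dm2);
        } else {
          fR = (i <= nx - 1 ? u[g.U(i + 1, j)] : 0.0) - 0.5 * minmod(dp2, dp1);
          fL = u[g.U(i, j)] - 0.5 * minmod(dp1, dm1);
        }
        double dudx = (fR - fL) / dx;
        double vbar = 0.25 * (v[g.V(i - 1, j)] + v[g.V(i, j)] +
                              v[g.V(i - 1, j + 1)] + v[g.V(i, j + 1)]);
        double em1 = ughost(i, j) - ughost(i, j - 1);
        double em2 = ughost(i, j - 1) - ughost(i, j - 2);
        double ep1 = ughost(i, j + 1) - ughost(i, j);
        double ep2 = ughost(i, j + 2) - ughost(i, j + 1);
        double gT, gB;
        if (vbar > 0.0) {
          gT = ughost(i, j) + 0.5 * minmod(ep1, em1);
          gB = ughost(i, j - 1) + 0.5 * minmod(em1, em2);
        } else {
          gT = ughost(i, j + 1) - 0.5 * minmod(ep2, ep1);
          gB = ughost(i, j) - 0.5 * minmod(ep1, em1);
        }
        double dudy = (gT - gB) / dy;

        double Vx = (2.0 * mu_c[g.C(i, j)] * (u[g.U(i + 1, j)] - u[g.U(i, j)]) -
                     2.0 * mu_c[g.C(i - 1, j)] * (u[g.U(i, j)] - u[g.U(i - 1, j)])) /
                    (dx * dx);
        double sxy_t = mu_corner(i, j + 1) *
          ((ughost(i, j + 1) - u[g.U(i, j)]) / dy +
           (v[g.V(i, j + 1)] - v[g.V(i - 1, j + 1)]) / dx);
        double sxy_b = mu_corner(i, j) *
          ((u[g.U(i, j)] - ughost(i, j - 1)) / dy +
           (v[g.V(i, j)] - v[g.V(i - 1, j)]) / dx);
        double Vy = (sxy_t - sxy_b) / dy;

        // CSF at face: gradient-weighted curvature, sharp grad(r)
        double wl = wgrad[g.C(i - 1, j)], wr = wgrad[g.C(i, j)];
        double kf = (wl + wr) > 0.0
          ? (wl * kappa[g.C(i - 1, j)] + wr * kappa[g.C(i, j)]) / (wl + wr)
          : 0.0;
        double Fx = sigma * kf * (r[g.C(i, j)] - r[g.C(i - 1, j)]) / dx;

        double gradp = (p[g.C(i, j)] - p[g.C(i - 1, j)]) / (dx * rhoF);
        us[g.U(i, j)] = u[g.U(i, j)] + dt * (-(ucen * dudx + vbar * dudy) +
                                             (Vx + Vy) / rhoF - gradp +
                                             Fx / rhoF + accx);
      }
      us[g.U(0, j)] = 0.0;
      us[g.U(nx, j)] = 0.0;
    }

    // v predictor (interior y-faces + top outlet faces)
    for (int j = 1; j <= ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double rhoF = (j < ny)
          ? 0.5 * (rho_c[g.C(i, j - 1)] + rho_c[g.C(i, j)])
          : rho_c[g.C(i, ny - 1)];
        double vcen = v[g.V(i, j)];
        double ubar = 0.25 * (ughost(i, j - 1) + ughost(i + 1, j - 1) +
                              ughost(i, j) + ughost(i + 1, j));
        double dm1 = vghost(i, j) - vghost(i - 1, j);
        double dm2 = vghost(i - 1, j) - vghost(i - 2, j);
        double dp1 = vghost(i + 1, j) - vghost(i, j);
        double dp2 = vghost(i + 2, j) - vghost(i + 1, j);
        double fR, fL;
        if (ubar > 0.0) {
          fR = vghost(i, j) + 0.5 * minmod(dp1, dm1);
          fL = vghost(i - 1, j) + 0.5 * minmod(dm1, dm2);
        } else {
          fR = vghost(i + 1, j) - 0.5 * minmod(dp2, dp1);
          fL = vghost(i, j) - 0.5 * minmod(dp1, dm1);
        }
        double dvdx = (fR - fL) / dx;
        double em1 = (j >= 1) ? v[g.V(i, j)] - v[g.V(i, j - 1)] : 0.0;
        double em2 = (j >= 2) ? v[g.V(i, j - 1)] - v[g.V(i, j - 2)] : 0.0;
        double ep1 = (j <= ny - 1) ? v[g.V(i, j + 1)] - v[g.V(i, j)]
                                   : vghost(i, j + 1) - v[g.V(i, j)];
        double ep2 = (j <= ny - 2) ? v[g.V(i, j + 2)] - v[g.V(i, j + 1)] : 0.0;
        double gT, gB;
        if (vcen > 0.0) {
          gT = v[g.V(i, j)] + 0.5 * minmod(ep1, em1);
          gB = v[g.V(i, j - 1)] + 0.5 * minmod(em1, em2);
        } else {
          gT = vghost(i, j + 1) - 0.5 * minmod(ep2, ep1);
          gB = v[g.V(i, j)] - 0.5 * minmod(ep1, em1);
        }
        double dvdy = (gT - gB) / dy;

        double mu_t = (j < ny) ? mu_c[g.C(i, j)] : mu_c[g.C(i, ny - 1)];
        double v_t = (j < ny) ? v[g.V(i, j + 1)] : vghost(i, j + 1);
        double Vy = (2.0 * mu_t * (v_t - v[g.V(i, j)]) -
                     2.0 * mu_c[g.C(i, j - 1)] * (v[g.V(i, j)] - v[g.V(i, j - 1)])) /
                    (dy * dy);
        double sxy_r = mu_corner(i + 1, j) *
          ((vghost(i + 1, j) - v[g.V(i, j)]) / dx +
           (ughost(i + 1, j) - ughost(i + 1, j - 1)) / dy);
        double sxy_l = mu_corner(i, j) *
          ((v[g.V(i, j)] - vghost(i - 1, j)) / dx +
           (ughost(i, j) - ughost(i, j - 1)) / dy);
        double Vx = (sxy_r - sxy_l) / dx;

        double Fy, gradp;
        if (j < ny) {
          double wb = wgrad[g.C(i, j - 1)], wt = wgrad[g.C(i, j)];
          double kf = (wb + wt) > 0.0
            ? (wb * kappa[g.C(i, j - 1)] + wt * kappa[g.C(i, j)]) / (wb + wt)
            : 0.0;
          Fy = sigma * kf * (r[g.C(i, j)] - r[g.C(i, j - 1)]) / dy;
          gradp = (p[g.C(i, j)] - p[g.C(i, j - 1)]) / (dy * rhoF);
        } else {
          Fy = 0.0;
          gradp = (-2.0 * p[g.C(i, ny - 1)]) / (dy * rhoF); // p = 0 at outlet
        }
        vs[g.V(i, j)] = v[g.V(i, j)] + dt * (-(ubar * dvdx + vcen * dvdy) +
                                             (Vx + Vy) / rhoF - gradp +
                                             Fy / rhoF - gravity);
      }
    }
    for (int i = 0; i < nx; ++i) vs[g.V(i, 0)] = 0.0;

    // --- PISO correctors
    int cg_total = 0;
    double div_max = 0.0;
    bool poisson_fail = false;
    {
      // coefficients of (-L); identical across correctors
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int k = g.C(i, j);
          double aE = 0.0, aW = 0.0, aN = 0.0, aS = 0.0;
          if (i < nx - 1) {
            double rf = 0.5 * (rho_c[k] + rho_c[g.C(i + 1, j)]);
            aE = dt / (rf * dx * dx);
          }
          if (i > 0) {
            double rf = 0.5 * (rho_c[k] + rho_c[g.C(i - 1, j)]);
            aW = dt / (rf * dx * dx);
          }
          if (j < ny - 1) {
            double rf = 0.5 * (rho_c[k] + rho_c[g.C(i, j + 1)]);
            aN = dt / (rf * dy * dy);
          } else {
            aN = 2.0 * dt / (rho_c[k] * dy * dy);   // Dirichlet p=0 on outlet
          }
          if (j > 0) {
            double rf = 0.5 * (rho_c[k] + rho_c[g.C(i, j - 1)]);
            aS = dt / (rf * dy * dy);
          }
          A.aE[k] = aE; A.aW[k] = aW; A.aN[k] = (j < ny - 1) ? aN : 0.0;
          A.aS[k] = aS;
          A.diag[k] = aE + aW + aS + ((j < ny - 1) ? aN : 2.0 * dt / (rho_c[k] * dy * dy));
        }
      ic0_factor(A, g);
    }
    for (int corr = 0; corr < n_correctors; ++corr) {
      double bnmax = 0.0;
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          b[g.C(i, j)] = (us[g.U(i + 1, j)] - us[g.U(i, j)]) / dx +
                         (vs[g.V(i, j + 1)] - vs[g.V(i, j)]) / dy;
          bnmax = std::max(bnmax, std::abs(b[g.C(i, j)]));
        }
      // warm-start the first corrector from the previous step's correction
      int iters = pcg_solve(A, g, b, pc, poisson_tol, max_poisson_iter,
                            last_res, corr == 0 && step > 1);
      if (iters < 0) { poisson_fail = true; break; }
      cg_total += iters;
      // correct
      for (int j = 0; j < ny; ++j) {
        for (int i = 1; i < nx; ++i) {
          double rf = 0.5 * (rho_c[g.C(i - 1, j)] + rho_c[g.C(i, j)]);
          us[g.U(i, j)] -= dt * (pc[g.C(i, j)] - pc[g.C(i - 1, j)]) / (dx * rf);
        }
      }
      for (int j = 1; j <= ny; ++j)
        for (int i = 0; i < nx; ++i) {
          if (j < ny) {
            double rf = 0.5 * (rho_c[g.C(i, j - 1)] + rho_c[g.C(i, j)]);
            vs[g.V(i, j)] -= dt * (pc[g.C(i, j)] - pc[g.C(i, j - 1)]) / (dy * rf);
          } else {
            double rf = rho_c[g.C(i, ny - 1)];
            vs[g.V(i, j)] -= dt * (-2.0 * pc[g.C(i, ny - 1)]) / (dy * rf);
          }
        }
      for (int k = 0; k < nx * ny; ++k) p[k] += pc[k];
    }
    if (poisson_fail) { status = "poisson_nonconvergence"; break; }
    u = us; v = vs;
    for (int j = 0; j < ny; ++j) { u[g.U(0, j)] = 0.0; u[g.U(nx, j)] = 0.0; }
    for (int i = 0; i < nx; ++i) v[g.V(i, 0)] = 0.0;

    // final divergence
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double dv = (u[g.U(i + 1, j)] - u[g.U(i, j)]) / dx +
                    (v[g.V(i, j + 1)] - v[g.V(i, j)]) / dy;
        div_max = std::max(div_max, std::abs(dv));
      }

    // --- VOF advection
    double clipped = vof_advect(r, u, v, g, dt, false, false, x_first);
    x_first = !x_first;

    t += dt;
    if (step % diag_every == 0 || t >= t_end - 1e-12)
      push_diag(t, dt, cg_total, div_max, clipped);
    if (snap_idx < snaps.size() && t >= snaps[snap_idx] - 1e-9) {
      store_snapshot(t);
      snap_idx++;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  int nrow = diag_rows.size() / NDIAG;
  NumericMatrix D(nrow, NDIAG);
  for (int rI = 0; rI < nrow; ++rI)
    for (int cI = 0; cI < NDIAG; ++cI)
      D(rI, cI) = diag_rows[rI * NDIAG + cI];
  colnames(D) = CharacterVector::create(
    "t", "dt", "vol_avg_speed", "max_liquid_speed", "wall_avg_wss", "max_wss",
    "interface_length", "v_interface", "liquid_volume", "div_max", "cg_iters",
    "clipped", "mixed_cells", "n_segments", "centroid_x");

  NumericMatrix Rf(nx, ny), Uf(nx + 1, ny), Vf(nx, ny + 1), Pf(nx, ny);
  std::copy(r.begin(), r.end(), Rf.begin());
  std::copy(u.begin(), u.end(), Uf.begin());
  std::copy(v.begin(), v.end(), Vf.begin());
  std::copy(p.begin(), p.end(), Pf.begin());

  return List::create(_["diagnostics"] = D, _["snapshots"] = snapshots,
                      _["r"] = Rf, _["u"] = Uf, _["v"] = Vf, _["p"] = Pf,
                      _["status"] = status, _["n_steps"] = step,
                      _["last_residual"] = last_res);
}
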
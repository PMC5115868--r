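// Numerical kernels: tricubic (Catmull-Rom) map interpolation, Gaussian-atom
// density simulation, Pearson CC with analytic gradients w.r.t. atom
// coordinates / B-factors / map voxel+origin, and bonded / repulsive
// geometry terms. All coordinates in Angstrom; grids are R arrays in
// column-major order with the x index fastest.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- Catmull-Rom cubic kernel ------------------------------------------

// weights for the 4 support nodes at fractional offset t in [0,1)
static inline void cr_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t + 2.0 * t2 - t3);
  w[1] = 0.5 * (2.0 - 5.0 * t2 + 3.0 * t3);
  w[2] = 0.5 * (t + 4.0 * t2 - 3.0 * t3);
  w[3] = 0.5 * (-t2 + t3);
}

static inline void cr_dweights(double t, double d[4]) {
  double t2 = t * t;
  d[0] = 0.5 * (-1.0 + 4.0 * t - 3.0 * t2);
  d[1] = 0.5 * (-10.0 * t + 9.0 * t2);
  d[2] = 0.5 * (1.0 + 8.0 * t - 9.0 * t2);
  d[3] = 0.5 * (-2.0 * t + 3.0 * t2);
}

struct Grid3 {
  const double *v;
  int nx, ny, nz;
  inline double at(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
    return v[i + (size_t)nx * (j + (size_t)ny * k)];
  }
};

// value + gradient (per index unit) at fractional index coords q[3];
// zero-padded outside support.
static inline void tricubic(const Grid3 &g, const double q[3],
                            double *val, double *grad) {
  // fully outside the padded support -> 0 value, 0 gradient
  if (q[0] <= -2.0 || q[1] <= -2.0 || q[2] <= -2.0 ||
      q[0] >= g.nx + 1.0 || q[1] >= g.ny + 1.0 || q[2] >= g.nz + 1.0) {
    *val = 0.0;
    if (grad) { grad[0] = grad[1] = grad[2] = 0.0; }
    return;
  }
  int b[3];
  double t[3], w[3][4], d[3][4];
  for (int a = 0; a < 3; ++a) {
    b[a] = (int)std::floor(q[a]);
    t[a] = q[a] - b[a];
    cr_weights(t[a], w[a]);
    if (grad) cr_dweights(t[a], d[a]);
  }
  double v = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
  for (int kk = 0; kk < 4; ++kk) {
    int k = b[2] - 1 + kk;
    for (int jj = 0; jj < 4; ++jj) {
      int j = b[1] - 1 + jj;
      double wjk = w[1][jj] * w[2][kk];
      for (int ii = 0; ii < 4; ++ii) {
        double f = g.at(b[0] - 1 + ii, j, k);
        if (f == 0.0) continue;
        v += f * w[0][ii] * wjk;
        if (grad) {
          gx += f * d[0][ii] * w[1][jj] * w[2][kk];
          gy += f * w[0][ii] * d[1][jj] * w[2][kk];
          gz += f * w[0][ii] * w[1][jj] * d[2][kk];
        }
      }
    }
  }
  *val = v;
  if (grad) { grad[0] = gx; grad[1] = gy; grad[2] = gz; }
}

// [[Rcpp::export]]
List cpp_interp(NumericVector map, IntegerVector dim, NumericMatrix qidx,
                bool gradient = true) {
  Grid3 g{map.begin(), dim[0], dim[1], dim[2]};
  int n = qidx.nrow();
  NumericVector val(n);
  NumericMatrix grad(n, 3);
  for (int i = 0; i < n; ++i) {
    double q[3] = {qidx(i, 0), qidx(i, 1), qidx(i, 2)};
    double v, gr[3];
    tricubic(g, q, &v, gradient ? gr : (double *)0);
    val[i] = v;
    if (gradient) { grad(i, 0) = gr[0]; grad(i, 1) = gr[1]; grad(i, 2) = gr[2]; }
  }
  return List::create(_["value"] = val, _["gradient"] = grad);
}

// ---- Gaussian-atom density ---------------------------------------------

// rho(x) = sum_i w_i / (2 pi s2_i)^{3/2} exp(-|x - x_i|^2 / (2 s2_i))
// [[Rcpp::export]]
NumericVector cpp_sim_density(NumericMatrix coords, NumericVector weight,
                              NumericVector sigma2, IntegerVector dim,
                              NumericVector voxel, NumericVector origin,
                              double nsigma = 4.0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  double *o = out.begin();
  int na = coords.nrow();
  for (int a = 0; a < na; ++a) {
    double s2 = sigma2[a];
    double amp = weight[a] / std::pow(2.0 * M_PI * s2, 1.5);
    if (amp == 0.0) continue;
    double cut = nsigma * std::sqrt(s2);
    double px = coords(a, 0), py = coords(a, 1), pz = coords(a, 2);
    int i0 = (int)std::ceil((px - cut - origin[0]) / voxel[0]);
    int i1 = (int)std::floor((px + cut - origin[0]) / voxel[0]);
    int j0 = (int)std::ceil((py - cut - origin[1]) / voxel[1]);
    int j1 = (int)std::floor((py + cut - origin[1]) / voxel[1]);
    int k0 = (int)std::ceil((pz - cut - origin[2]) / voxel[2]);
    int k1 = (int)std::floor((pz + cut - origin[2]) / voxel[2]);
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
    if (i1 >= nx) i1 = nx - 1; if (j1 >= ny) j1 = ny - 1; if (k1 >= nz) k1 = nz - 1;
    double inv2s2 = 1.0 / (2.0 * s2);
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * voxel[2] - pz, dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * voxel[1] - py, dy2 = dy * dy;
        size_t base = (size_t)nx * (j + (size_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * voxel[0] - px;
          double r2 = dx * dx + dy2 + dz2;
          o[base + i] += amp * std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Pearson CC between simulated density (from atoms) and an observed map,
// optionally weighted, with analytic gradients w.r.t. atom coordinates and
// sigma2 (for B-factor fitting).
// [[Rcpp::export]]
List cpp_density_cc(NumericMatrix coords, NumericVector weight,
                    NumericVector sigma2, NumericVector map,
                    IntegerVector dim, NumericVector voxel,
                    NumericVector origin, NumericVector wts,
                    double nsigma = 4.0, bool grad_xyz = true,
                    bool grad_s2 = false) {
  NumericVector sim = cpp_sim_density(coords, weight, sigma2, dim, voxel,
                                      origin, nsigma);
  size_t nv = sim.size();
  bool havew = wts.size() == (R_xlen_t)nv;
  const double *x = sim.begin(), *y = map.begin();
  double W = 0, Sx = 0, Sy = 0, Sxx = 0, Syy = 0, Sxy = 0;
  for (size_t v = 0; v < nv; ++v) {
    double w = havew ? wts[v] : 1.0;
    if (w == 0.0) continue;
    W += w; Sx += w * x[v]; Sy += w * y[v];
    Sxx += w * x[v] * x[v]; Syy += w * y[v] * y[v]; Sxy += w * x[v] * y[v];
  }
  double xb = Sx / W, yb = Sy / W;
  double Cxx = Sxx / W - xb * xb, Cyy = Syy / W - yb * yb;
  double Cxy = Sxy / W - xb * yb;
  if (Cxx <= 0 || Cyy <= 0)
    return List::create(_["cc"] = NA_REAL);
  double denom = std::sqrt(Cxx * Cyy);
  double cc = Cxy / denom;

  int na = coords.nrow();
  NumericMatrix gxyz(grad_xyz ? na : 0, 3);
  NumericVector gs2(grad_s2 ? na : 0);
  if (grad_xyz || grad_s2) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    // dCC/dx_v = (w_v/W) * [ (y_v - yb) - (Cxy/Cxx)(x_v - xb) ] / denom
    for (int a = 0; a < na; ++a) {
      double s2 = sigma2[a];
      double amp = weight[a] / std::pow(2.0 * M_PI * s2, 1.5);
      double cut = nsigma * std::sqrt(s2);
      double px = coords(a, 0), py = coords(a, 1), pz = coords(a, 2);
      int i0 = (int)std::ceil((px - cut - origin[0]) / voxel[0]);
      int i1 = (int)std::floor((px + cut - origin[0]) / voxel[0]);
      int j0 = (int)std::ceil((py - cut - origin[1]) / voxel[1]);
      int j1 = (int)std::floor((py + cut - origin[1]) / voxel[1]);
      int k0 = (int)std::ceil((pz - cut - origin[2]) / voxel[2]);
      int k1 = (int)std::floor((pz + cut - origin[2]) / voxel[2]);
      if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
      if (i1 >= nx) i1 = nx - 1; if (j1 >= ny) j1 = ny - 1; if (k1 >= nz) k1 = nz - 1;
      double inv2s2 = 1.0 / (2.0 * s2);
      double ax = 0, ay = 0, az = 0, as2 = 0;
      for (int k = k0; k <= k1; ++k) {
        double dz = origin[2] + k * voxel[2] - pz;
        for (int j = j0; j <= j1; ++j) {
          double dy = origin[1] + j * voxel[1] - py;
          size_t base = (size_t)nx * (j + (size_t)ny * k);
          for (int i = i0; i <= i1; ++i) {
            size_t v = base + i;
            double w = havew ? wts[v] : 1.0;
            if (w == 0.0) continue;
            double dx = origin[0] + i * voxel[0] - px;
            double r2 = dx * dx + dy * dy + dz * dz;
            double gdens = amp * std::exp(-r2 * inv2s2);
            double resid = (w / W) *
              ((y[v] - yb) - (Cxy / Cxx) * (x[v] - xb)) / denom;
            double f = resid * gdens;
            // d gdens / d atom position = gdens * (x_v - x_a)/s2
            ax += f * dx / s2;
            ay += f * dy / s2;
            az += f * dz / s2;
            if (grad_s2)
              as2 += f * (r2 / (2.0 * s2 * s2) - 1.5 / s2);
          }
        }
      }
      if (grad_xyz) { gxyz(a, 0) = ax; gxyz(a, 1) = ay; gxyz(a, 2) = az; }
      if (grad_s2) gs2[a] = as2;
    }
  }
  return List::create(_["cc"] = cc, _["grad_xyz"] = gxyz,
                      _["grad_sigma2"] = gs2, _["sim"] = sim);
}

// ---- CC of observed map vs resampled model density ---------------------

// Observed voxel (i,j,k) is placed at world position orig_new + idx * vox_new
// and the model density (fixed geometry c_origin/c_voxel) is sampled there
// with tricubic splines. Returns Pearson CC over all voxels (or where
// mask != 0) and analytic gradients w.r.t. vox_new (3) and orig_new (3).
// [[Rcpp::export]]
List cpp_resample_cc(NumericVector rho_o, IntegerVector dim,
                     NumericVector rho_c, IntegerVector cdim,
                     NumericVector c_voxel, NumericVector c_origin,
                     NumericVector vox_new, NumericVector orig_new,
                     NumericVector mask) {
  const double *c = rho_c.begin();
  int cnx = cdim[0], cny = cdim[1], cnz = cdim[2];
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nv = (size_t)nx * ny * nz;
  bool havem = mask.size() == (R_xlen_t)nv;
  const double *x = rho_o.begin();
  // the resampling position is separable per axis: precompute base indices
  // and Catmull-Rom weights/derivative-weights for every grid index
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<int> base(3 * nmax);
  std::vector<double> wgt(3 * nmax * 4), dwgt(3 * nmax * 4);
  std::vector<char> inside(3 * nmax);
  int dims[3] = {nx, ny, nz}, cdims[3] = {cnx, cny, cnz};
  for (int a = 0; a < 3; ++a) {
    for (int i = 0; i < dims[a]; ++i) {
      double q = (orig_new[a] + i * vox_new[a] - c_origin[a]) / c_voxel[a];
      int b = (int)std::floor(q);
      double t = q - b;
      base[a * nmax + i] = b;
      inside[a * nmax + i] = (q > -2.0 && q < cdims[a] + 1.0);
      cr_weights(t, &wgt[(a * nmax + i) * 4]);
      cr_dweights(t, &dwgt[(a * nmax + i) * 4]);
    }
  }
  double W = 0, Sx = 0, Sy = 0, Sxx = 0, Syy = 0, Sxy = 0;
  std::vector<double> Sd(6, 0.0), Sxd(6, 0.0), Syd(6, 0.0);
  size_t v = 0;
  for (int k = 0; k < nz; ++k) {
    const double *wz = &wgt[(2 * nmax + k) * 4], *dz = &dwgt[(2 * nmax + k) * 4];
    int bz = base[2 * nmax + k];
    for (int j = 0; j < ny; ++j) {
      const double *wy = &wgt[(1 * nmax + j) * 4], *dyv = &dwgt[(1 * nmax + j) * 4];
      int by = base[1 * nmax + j];
      bool in_jk = inside[2 * nmax + k] && inside[1 * nmax + j];
      for (int i = 0; i < nx; ++i, ++v) {
        double w = havem ? mask[v] : 1.0;
        if (w == 0.0) continue;
        double val = 0, gr[3] = {0, 0, 0};
        if (in_jk && inside[0 * nmax + i]) {
          const double *wx = &wgt[i * 4], *dx = &dwgt[i * 4];
          int bx = base[i];
          for (int kk = 0; kk < 4; ++kk) {
            int zz = bz - 1 + kk;
            if (zz < 0 || zz >= cnz) continue;
            for (int jj = 0; jj < 4; ++jj) {
              int yy = by - 1 + jj;
              if (yy < 0 || yy >= cny) continue;
              const double *col = c + (size_t)cnx * (yy + (size_t)cny * zz);
              double s_v = 0, s_d = 0;
              for (int ii = 0; ii < 4; ++ii) {
                int xx = bx - 1 + ii;
                if (xx < 0 || xx >= cnx) continue;
                double f = col[xx];
                s_v += f * wx[ii];
                s_d += f * dx[ii];
              }
              double wjk = wy[jj] * wz[kk];
              val += s_v * wjk;
              gr[0] += s_d * wjk;
              gr[1] += s_v * dyv[jj] * wz[kk];
              gr[2] += s_v * wy[jj] * dz[kk];
            }
          }
        }
        // d val / d orig_new[a] = gr[a]/c_voxel[a];
        // d val / d vox_new[a]  = gr[a]*idx[a]/c_voxel[a]
        double idx3[3] = {(double)i, (double)j, (double)k};
        double d6[6];
        for (int a = 0; a < 3; ++a) {
          double go = gr[a] / c_voxel[a];
          d6[a] = go * idx3[a]; // voxel-size params first
          d6[3 + a] = go;       // then origin params
        }
        W += w; Sx += w * x[v]; Sy += w * val;
        Sxx += w * x[v] * x[v]; Syy += w * val * val; Sxy += w * x[v] * val;
        for (int p = 0; p < 6; ++p) {
          Sd[p] += w * d6[p];
          Sxd[p] += w * x[v] * d6[p];
          Syd[p] += w * val * d6[p];
        }
      }
    }
  }
  double xb = Sx / W, yb = Sy / W;
  double Cxx = Sxx / W - xb * xb, Cyy = Syy / W - yb * yb;
  double Cxy = Sxy / W - xb * yb;
  if (Cxx <= 1e-300 || Cyy <= 1e-300)
    return List::create(_["cc"] = NA_REAL);
  double denom = std::sqrt(Cxx * Cyy);
  double cc = Cxy / denom;
  NumericVector gv(3), go(3);
  for (int p = 0; p < 6; ++p) {
    double dCxy = Sxd[p] / W - xb * (Sd[p] / W);
    double dCyy = 2.0 * (Syd[p] / W - yb * (Sd[p] / W));
    double dcc = dCxy / denom - 0.5 * cc * dCyy / Cyy;
    if (p < 3) gv[p] = dcc; else go[p - 3] = dcc;
  }
  return List::create(_["cc"] = cc, _["grad_voxel"] = gv,
                      _["grad_origin"] = go);
}

// ---- bonded geometry ----------------------------------------------------

static inline void cross3(const double a[3], const double b[3], double o[3]) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double a[3]) { return std::sqrt(dot3(a, a)); }

// dihedral value and (optionally) gradient w.r.t. the four atoms
static double dihedral(const double *r1, const double *r2, const double *r3,
                       const double *r4, double *g /* 12 or NULL */) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m[3];
  for (int a = 0; a < 3; ++a) {
    b1[a] = r2[a] - r1[a];
    b2[a] = r3[a] - r2[a];
    b3[a] = r4[a] - r3[a];
  }
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  double lb2 = norm3(b2);
  cross3(n1, n2, m);
  double phi = std::atan2(dot3(m, b2) / lb2, dot3(n1, n2));
  if (g) {
    double in1 = dot3(n1, n1), in2 = dot3(n2, n2);
    if (in1 < 1e-12 || in2 < 1e-12) {
      for (int a = 0; a < 12; ++a) g[a] = 0;
      return phi;
    }
    double d1[3], d4[3];
    for (int a = 0; a < 3; ++a) {
      d1[a] = -lb2 / in1 * n1[a];
      d4[a] = lb2 / in2 * n2[a];
    }
    double c12 = dot3(b1, b2) / (lb2 * lb2), c32 = dot3(b3, b2) / (lb2 * lb2);
    for (int a = 0; a < 3; ++a) {
      g[a] = d1[a];
      g[3 + a] = -(1.0 + c12) * d1[a] + c32 * d4[a];
      g[6 + a] = c12 * d1[a] - (1.0 + c32) * d4[a];
      g[9 + a] = d4[a];
    }
  }
  return phi;
}

// [[Rcpp::export]]
NumericVector cpp_dihedrals(NumericMatrix coords, IntegerMatrix quads) {
  int n = quads.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double r[4][3];
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) r[a][c] = coords(quads(q, a) - 1, c);
    out[q] = dihedral(r[0], r[1], r[2], r[3], (double *)0);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dihedral_grad(NumericMatrix coords, IntegerMatrix quads) {
  int n = quads.nrow();
  NumericVector ang(n);
  NumericMatrix grad(n, 12);
  for (int q = 0; q < n; ++q) {
    double r[4][3], g[12];
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) r[a][c] = coords(quads(q, a) - 1, c);
    ang[q] = dihedral(r[0], r[1], r[2], r[3], g);
    for (int a = 0; a < 12; ++a) grad(q, a) = g[a];
  }
  return List::create(_["angle"] = ang, _["gradient"] = grad);
}

static inline double wrap_pi(double x) {
  while (x > M_PI) x -= 2.0 * M_PI;
  while (x < -M_PI) x += 2.0 * M_PI;
  return x;
}

// Harmonic bonded strain: bonds 0.5 k (d-d0)^2, angles 0.5 k (th-th0)^2,
// planarity torsions 0.5 k wrap(phi-phi0)^2. Per-term energies returned so
// the caller can attribute them to residues; gradient is optional.
// [[Rcpp::export]]
List cpp_bonded(NumericMatrix coords,
                IntegerMatrix bond_idx, NumericVector bond_d0, NumericVector bond_k,
                IntegerMatrix ang_idx, NumericVector ang_t0, NumericVector ang_k,
                IntegerMatrix tor_idx, NumericVector tor_t0, NumericVector tor_k,
                bool gradient = true) {
  int na = coords.nrow();
  NumericMatrix grad(gradient ? na : 0, 3);
  int nb = bond_idx.nrow(), ng = ang_idx.nrow(), nt = tor_idx.nrow();
  NumericVector eb(nb), ea(ng), et(nt);
  for (int b = 0; b < nb; ++b) {
    int i = bond_idx(b, 0) - 1, j = bond_idx(b, 1) - 1;
    double d[3];
    for (int c = 0; c < 3; ++c) d[c] = coords(i, c) - coords(j, c);
    double L = norm3(d);
    double dev = L - bond_d0[b];
    eb[b] = 0.5 * bond_k[b] * dev * dev;
    if (gradient && L > 1e-9) {
      double f = bond_k[b] * dev / L;
      for (int c = 0; c < 3; ++c) {
        grad(i, c) += f * d[c];
        grad(j, c) -= f * d[c];
      }
    }
  }
  for (int q = 0; q < ng; ++q) {
    int i = ang_idx(q, 0) - 1, j = ang_idx(q, 1) - 1, k = ang_idx(q, 2) - 1;
    double u[3], w[3];
    for (int c = 0; c < 3; ++c) {
      u[c] = coords(i, c) - coords(j, c);
      w[c] = coords(k, c) - coords(j, c);
    }
    double lu = norm3(u), lw = norm3(w);
    double ct = dot3(u, w) / (lu * lw);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double dev = th - ang_t0[q];
    ea[q] = 0.5 * ang_k[q] * dev * dev;
    if (gradient) {
      double st = std::sqrt(1.0 - ct * ct);
      if (st < 1e-6) st = 1e-6;
      double gi[3], gk[3];
      for (int c = 0; c < 3; ++c) {
        gi[c] = (ct * u[c] / lu - w[c] / lw) / (lu * st);
        gk[c] = (ct * w[c] / lw - u[c] / lu) / (lw * st);
      }
      double f = ang_k[q] * dev;
      for (int c = 0; c < 3; ++c) {
        grad(i, c) += f * gi[c];
        grad(k, c) += f * gk[c];
        grad(j, c) -= f * (gi[c] + gk[c]);
      }
    }
  }
  for (int q = 0; q < nt; ++q) {
    double r[4][3], g[12];
    int id[4];
    for (int a = 0; a < 4; ++a) {
      id[a] = tor_idx(q, a) - 1;
      for (int c = 0; c < 3; ++c) r[a][c] = coords(id[a], c);
    }
    double phi = dihedral(r[0], r[1], r[2], r[3], gradient ? g : (double *)0);
    double dev = wrap_pi(phi - tor_t0[q]);
    et[q] = 0.5 * tor_k[q] * dev * dev;
    if (gradient) {
      double f = tor_k[q] * dev;
      for (int a = 0; a < 4; ++a)
        for (int c = 0; c < 3; ++c) grad(id[a], c) += f * g[3 * a + c];
    }
  }
  return List::create(_["bond_e"] = eb, _["angle_e"] = ea, _["torsion_e"] = et,
                      _["gradient"] = grad);
}

// Soft-sphere repulsion between non-bonded atoms (pairs separated by > 2
// residues-in-sequence positions or on different chains are counted;
// |resno difference| <= 1 within a chain is excluded as bonded context).
// E = sum 0.5 w (r0 - d)^2 for d < r0, r0 = rad_i + rad_j - tol.
// [[Rcpp::export]]
List cpp_clash(NumericMatrix coords, NumericVector radii, IntegerVector resno,
               IntegerVector chain, double w, double tol,
               bool gradient = true, double count_overlap = 0.4) {
  int n = coords.nrow();
  NumericMatrix grad(gradient ? n : 0, 3);
  double E = 0.0;
  int nclash = 0;
  // cell list: bin atoms at the maximum interaction distance, scan 27 cells
  double rmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  double cell = 2.0 * rmax;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) lo[c] = std::min(lo[c], coords(i, c));
  int nc[3];
  std::vector<int> ci(3 * n);
  for (int c = 0; c < 3; ++c) nc[c] = 1;
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      ci[3 * i + c] = (int)((coords(i, c) - lo[c]) / cell);
      nc[c] = std::max(nc[c], ci[3 * i + c] + 1);
    }
  std::vector<std::vector<int> > bins((size_t)nc[0] * nc[1] * nc[2]);
  for (int i = 0; i < n; ++i)
    bins[ci[3 * i] + (size_t)nc[0] * (ci[3 * i + 1] + (size_t)nc[1] * ci[3 * i + 2])]
      .push_back(i);
  for (int i = 0; i < n; ++i) {
    for (int dz = -1; dz <= 1; ++dz) {
      int z = ci[3 * i + 2] + dz;
      if (z < 0 || z >= nc[2]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = ci[3 * i + 1] + dy;
        if (y < 0 || y >= nc[1]) continue;
        for (int dxc = -1; dxc <= 1; ++dxc) {
          int xc = ci[3 * i] + dxc;
          if (xc < 0 || xc >= nc[0]) continue;
          const std::vector<int> &b =
            bins[xc + (size_t)nc[0] * (y + (size_t)nc[1] * z)];
          for (size_t bi = 0; bi < b.size(); ++bi) {
            int j = b[bi];
            if (j <= i) continue;
            if (chain[i] == chain[j] && std::abs(resno[i] - resno[j]) <= 1)
              continue;
            double d[3];
            for (int c = 0; c < 3; ++c) d[c] = coords(i, c) - coords(j, c);
            double r0 = radii[i] + radii[j] - tol;
            double hard = radii[i] + radii[j];
            if (std::fabs(d[0]) > hard || std::fabs(d[1]) > hard ||
                std::fabs(d[2]) > hard)
              continue;
            double L = norm3(d);
            if (hard - L > count_overlap) ++nclash;
            if (L < r0 && L > 1e-9) {
              double dev = r0 - L;
              E += 0.5 * w * dev * dev;
              if (gradient) {
                double f = -w * dev / L;
                for (int c = 0; c < 3; ++c) {
                  grad(i, c) += f * d[c];
                  grad(j, c) -= f * d[c];
                }
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["energy"] = E, _["n_clash"] = nclash,
                      _["gradient"] = grad);
}
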
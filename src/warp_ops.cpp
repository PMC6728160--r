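#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// 3D grids are column-major R arrays indexed [i + nx*(j + ny*k)], 0-based.

static inline double sample_trilinear(const double* d, int nx, int ny, int nz,
                                      double x, double y, double z, double oob) {
  if (x < -0.5 || y < -0.5 || z < -0.5 || x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
    return oob;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk) {
    int k = k0 + dk;
    double wz = dk ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj;
      double wy = dj ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di;
        double wx = di ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        double v = (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
                       ? oob
                       : d[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        acc += wx * wy * wz * v;
      }
    }
  }
  return acc;
}

static inline double sample_nearest(const double* d, int nx, int ny, int nz,
                                    double x, double y, double z, double oob) {
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return oob;
  return d[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
}

// Pull-back warp: out voxel v -> source voxel u = M v + t; sample the source.
// [[Rcpp::export]]
NumericVector cpp_warp_affine(const NumericVector& data, const IntegerVector& dims,
                              const NumericMatrix& M, const NumericVector& t,
                              const IntegerVector& out_dims, bool nearest, double oob) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* d = data.begin();
  double* o = out.begin();
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double x = M(0, 0) * i + M(0, 1) * j + M(0, 2) * k + t[0];
        double y = M(1, 0) * i + M(1, 1) * j + M(1, 2) * k + t[1];
        double z = M(2, 0) * i + M(2, 1) * j + M(2, 2) * k + t[2];
        o[i + (R_xlen_t)ox * (j + (R_xlen_t)oy * k)] =
            nearest ? sample_nearest(d, nx, ny, nz, x, y, z, oob)
                    : sample_trilinear(d, nx, ny, nz, x, y, z, oob);
      }
  out.attr("dim") = out_dims;
  return out;
}

// As cpp_warp_affine but with an additional dense displacement field (in source
// voxel units) defined on the output lattice: u = M v + t + disp(v).
// disp has dims (ox, oy, oz, 3).
// [[Rcpp::export]]
NumericVector cpp_warp_disp(const NumericVector& data, const IntegerVector& dims,
                            const NumericMatrix& M, const NumericVector& t,
                            const NumericVector& disp, const IntegerVector& out_dims,
                            bool nearest, double oob) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  const R_xlen_t V = (R_xlen_t)ox * oy * oz;
  NumericVector out(V);
  const double* d = data.begin();
  const double* u = disp.begin();
  double* o = out.begin();
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        const R_xlen_t v = i + (R_xlen_t)ox * (j + (R_xlen_t)oy * k);
        double x = M(0, 0) * i + M(0, 1) * j + M(0, 2) * k + t[0] + u[v];
        double y = M(1, 0) * i + M(1, 1) * j + M(1, 2) * k + t[1] + u[v + V];
        double z = M(2, 0) * i + M(2, 1) * j + M(2, 2) * k + t[2] + u[v + 2 * V];
        o[v] = nearest ? sample_nearest(d, nx, ny, nz, x, y, z, oob)
                       : sample_trilinear(d, nx, ny, nz, x, y, z, oob);
      }
  out.attr("dim") = out_dims;
  return out;
}

// Separable Gaussian smoothing with reflected boundaries; sigma in voxels.
static void smooth_axis(std::vector<double>& buf, double* d, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (auto& v : ker) v /= s;
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int len = n[axis];
  const R_xlen_t st = stride[axis];
  const int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  for (int p2 = 0; p2 < n[a2]; ++p2)
    for (int p1 = 0; p1 < n[a1]; ++p1) {
      double* line0 = d + stride[a1] * p1 + stride[a2] * p2;
      for (int i = 0; i < len; ++i) buf[i] = line0[st * i];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int q = -r; q <= r; ++q) {
          int idx = i + q;
          if (idx < 0) idx = -idx - 1;
          if (idx >= len) idx = 2 * len - idx - 1;
          idx = std::max(0, std::min(len - 1, idx));
          acc += ker[q + r] * buf[idx];
        }
        line0[st * i] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth3(const NumericVector& data, const IntegerVector& dims,
                                   const NumericVector& sigma) {
  NumericVector out(clone(data));
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  smooth_axis(buf, out.begin(), nx, ny, nz, 0, sigma[0]);
  smooth_axis(buf, out.begin(), nx, ny, nz, 1, sigma[1]);
  smooth_axis(buf, out.begin(), nx, ny, nz, 2, sigma[2]);
  out.attr("dim") = dims;
  return out;
}

// Cubic B-spline basis.
static inline void bspline_w(double u, double* w) {
  const double u2 = u * u, u3 = u2 * u;
  w[0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  w[1] = (3 * u3 - 6 * u2 + 4) / 6.0;
  w[2] = (-3 * u3 + 3 * u2 + 3 * u + 1) / 6.0;
  w[3] = u3 / 6.0;
}

// FFD control lattice: coef has dims (ncx, ncy, ncz, 3); control point with
// array index a sits at voxel position (a - 1) * delta along each axis, so the
// displacement at voxel v uses controls floor(v/delta)-1 .. +2 mapped to array
// indices floor(v/delta) .. +3.
// [[Rcpp::export]]
NumericVector cpp_ffd_eval_dense(const NumericVector& coef, const IntegerVector& nc,
                                 const NumericVector& delta, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ncx = nc[0], ncy = nc[1], ncz = nc[2];
  const R_xlen_t NC = (R_xlen_t)ncx * ncy * ncz;
  const R_xlen_t V = (R_xlen_t)nx * ny * nz;
  NumericVector out(V * 3);
  const double* c = coef.begin();
  double* o = out.begin();
  double wx[4], wy[4], wz[4];
  for (int k = 0; k < nz; ++k) {
    const double tz = k / delta[2];
    const int kz = (int)std::floor(tz);
    bspline_w(tz - kz, wz);
    for (int j = 0; j < ny; ++j) {
      const double ty = j / delta[1];
      const int jy = (int)std::floor(ty);
      bspline_w(ty - jy, wy);
      for (int i = 0; i < nx; ++i) {
        const double tx = i / delta[0];
        const int ix = (int)std::floor(tx);
        bspline_w(tx - ix, wx);
        double acc[3] = {0, 0, 0};
        for (int n = 0; n < 4; ++n) {
          const int ck = kz + n;
          if (ck < 0 || ck >= ncz) continue;
          for (int m = 0; m < 4; ++m) {
            const int cj = jy + m;
            if (cj < 0 || cj >= ncy) continue;
            const double wyz = wy[m] * wz[n];
            for (int l = 0; l < 4; ++l) {
              const int ci = ix + l;
              if (ci < 0 || ci >= ncx) continue;
              const double w = wx[l] * wyz;
              const R_xlen_t b = ci + (R_xlen_t)ncx * (cj + (R_xlen_t)ncy * ck);
              acc[0] += w * c[b];
              acc[1] += w * c[b + NC];
              acc[2] += w * c[b + 2 * NC];
            }
          }
        }
        const R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        o[v] = acc[0];
        o[v + V] = acc[1];
        o[v + 2 * V] = acc[2];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// Label-consistency surrogate objective and its gradient w.r.t. FFD control
// displacements. prob: atlas per-class probability channels (pnx,pny,pnz,K)
// on the atlas lattice; qprob: target per-class probability channels
// (tdims, K); mapping u(v) = M v + t + base(v) + ffd(v), all in atlas voxel
// units. Objective = mean_v sum_k q_k(v) * p_k(u(v)) -- the soft diagonal of
// the joint label probability, whose optimum for identical inputs is the
// identity (autocorrelation). Channels with negligible q at a voxel are
// skipped. An optional mask (target lattice; length 0 means none) restricts
// the objective to covered voxels, e.g. the slices actually acquired for a
// truncated low-resolution target.
// [[Rcpp::export]]
List cpp_ffd_obj_grad(const NumericVector& prob, const IntegerVector& pdims, int K,
                      const NumericVector& qprob, const IntegerVector& tdims,
                      const NumericMatrix& M, const NumericVector& t,
                      const NumericVector& base, bool has_base,
                      const NumericVector& coef, const IntegerVector& nc,
                      const NumericVector& delta, bool want_grad,
                      const LogicalVector& mask) {
  const int pnx = pdims[0], pny = pdims[1], pnz = pdims[2];
  const int nx = tdims[0], ny = tdims[1], nz = tdims[2];
  const int ncx = nc[0], ncy = nc[1], ncz = nc[2];
  const R_xlen_t NC = (R_xlen_t)ncx * ncy * ncz;
  const R_xlen_t PV = (R_xlen_t)pnx * pny * pnz;
  const R_xlen_t V = (R_xlen_t)nx * ny * nz;
  const double* pr = prob.begin();
  const double* qr = qprob.begin();
  const double* bs = base.begin();
  const double* c = coef.begin();
  const bool has_mask = mask.size() > 0;
  const int* mk = mask.begin();
  R_xlen_t nmask = 0;
  if (has_mask) {
    for (R_xlen_t q = 0; q < mask.size(); ++q) nmask += mk[q] ? 1 : 0;
    if (nmask == 0) nmask = 1;
  }
  NumericVector grad(want_grad ? NC * 3 : 1);
  double* g = grad.begin();
  double obj = 0.0;
  double wx[4], wy[4], wz[4];
  for (int k = 0; k < nz; ++k) {
    const double tz = k / delta[2];
    const int kz = (int)std::floor(tz);
    bspline_w(tz - kz, wz);
    for (int j = 0; j < ny; ++j) {
      const double ty = j / delta[1];
      const int jy = (int)std::floor(ty);
      bspline_w(ty - jy, wy);
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t vmask = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (has_mask && !mk[vmask]) continue;
        const double tx = i / delta[0];
        const int ix = (int)std::floor(tx);
        bspline_w(tx - ix, wx);
        // FFD displacement at v
        double u0 = 0, u1 = 0, u2 = 0;
        for (int n = 0; n < 4; ++n) {
          const int ck = kz + n;
          if (ck < 0 || ck >= ncz) continue;
          for (int m = 0; m < 4; ++m) {
            const int cj = jy + m;
            if (cj < 0 || cj >= ncy) continue;
            const double wyz = wy[m] * wz[n];
            for (int l = 0; l < 4; ++l) {
              const int ci = ix + l;
              if (ci < 0 || ci >= ncx) continue;
              const double w = wx[l] * wyz;
              const R_xlen_t b = ci + (R_xlen_t)ncx * (cj + (R_xlen_t)ncy * ck);
              u0 += w * c[b];
              u1 += w * c[b + NC];
              u2 += w * c[b + 2 * NC];
            }
          }
        }
        const R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double x = M(0, 0) * i + M(0, 1) * j + M(0, 2) * k + t[0] + u0;
        double y = M(1, 0) * i + M(1, 1) * j + M(1, 2) * k + t[1] + u1;
        double z = M(2, 0) * i + M(2, 1) * j + M(2, 2) * k + t[2] + u2;
        if (has_base) {
          x += bs[v];
          y += bs[v + V];
          z += bs[v + 2 * V];
        }
        // trilinear sample of each needed channel, with gradient; positions
        // are clamped to the domain (border padding) so the objective stays
        // continuous at the grid edge, with zero gradient in a clamped axis
        bool clx = false, cly = false, clz = false;
        if (x < 0) { x = 0; clx = true; } else if (x > pnx - 1) { x = pnx - 1; clx = true; }
        if (y < 0) { y = 0; cly = true; } else if (y > pny - 1) { y = pny - 1; cly = true; }
        if (z < 0) { z = 0; clz = true; } else if (z > pnz - 1) { z = pnz - 1; clz = true; }
        int i0 = std::min((int)std::floor(x), pnx - 2);
        int j0 = std::min((int)std::floor(y), pny - 2);
        int k0 = std::min((int)std::floor(z), pnz - 2);
        if (pnx == 1) i0 = 0;
        if (pny == 1) j0 = 0;
        if (pnz == 1) k0 = 0;
        const double fx = x - i0, fy = y - j0, fz = z - k0;
        double val = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
        for (int cls = 0; cls < K; ++cls) {
          const double qv = qr[v + (R_xlen_t)V * cls];
          if (qv < 1e-4) continue;
          const double* ch = pr + PV * cls;
          for (int dk = 0; dk <= 1; ++dk) {
            const int kk = std::min(k0 + dk, pnz - 1);
            const double wz2 = (dk ? fz : 1.0 - fz) * qv;
            const double dwz = dk ? qv : -qv;
            for (int dj = 0; dj <= 1; ++dj) {
              const int jj = std::min(j0 + dj, pny - 1);
              const double wy2 = dj ? fy : 1.0 - fy;
              const double dwy = dj ? 1.0 : -1.0;
              for (int di = 0; di <= 1; ++di) {
                const int ii = std::min(i0 + di, pnx - 1);
                const double wx2 = di ? fx : 1.0 - fx;
                const double dwx = di ? 1.0 : -1.0;
                const double pv = ch[ii + (R_xlen_t)pnx * (jj + (R_xlen_t)pny * kk)];
                val += wx2 * wy2 * wz2 * pv;
                gx += dwx * wy2 * wz2 * pv;
                gy += wx2 * dwy * wz2 * pv;
                gz += wx2 * wy2 * dwz * pv;
              }
            }
          }
        }
        if (clx) gx = 0.0;
        if (cly) gy = 0.0;
        if (clz) gz = 0.0;
        obj += val;
        if (want_grad) {
          for (int n = 0; n < 4; ++n) {
            const int ck = kz + n;
            if (ck < 0 || ck >= ncz) continue;
            for (int m = 0; m < 4; ++m) {
              const int cj = jy + m;
              if (cj < 0 || cj >= ncy) continue;
              const double wyz = wy[m] * wz[n];
              for (int l = 0; l < 4; ++l) {
                const int ci = ix + l;
                if (ci < 0 || ci >= ncx) continue;
                const double w = wx[l] * wyz;
                const R_xlen_t b = ci + (R_xlen_t)ncx * (cj + (R_xlen_t)ncy * ck);
                g[b] += w * gx;
                g[b + NC] += w * gy;
                g[b + 2 * NC] += w * gz;
              }
            }
          }
        }
      }
    }
  }
  const double denom = has_mask ? (double)nmask : (double)V;
  obj /= denom;
  List out = List::create(_["value"] = obj);
  if (want_grad) {
    for (R_xlen_t q = 0; q < NC * 3; ++q) g[q] /= denom;
    grad.attr("dim") = IntegerVector::create(ncx, ncy, ncz, 3);
    out["grad"] = grad;
  }
  return out;
}
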
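#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Boundary voxels of a binary mask under a 26-connectivity surface: a mask
// voxel is boundary if any of its 26 neighbours is outside the mask or beyond
// the grid edge.
// [[Rcpp::export]]
LogicalVector cpp_boundary_mask(const LogicalVector& mask, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const int* m = mask.begin();
  int* o = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!m[v]) continue;
        bool bnd = false;
        for (int dk = -1; dk <= 1 && !bnd; ++dk)
          for (int dj = -1; dj <= 1 && !bnd; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz ||
                  !m[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]) {
                bnd = true;
                break;
              }
            }
        o[v] = bnd;
      }
  out.attr("dim") = dims;
  return out;
}

// 1D squared distance transform (Felzenszwalb-Huttenlocher lower envelope)
// on sample positions i*step.
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -R_PosInf;
  z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    const double xq = q * step;
    double s;
    while (true) {
      const double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * step;
    while (z[k + 1] < xq) ++k;
    const double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact squared Euclidean distance transform of a voxel set (true at seeds),
// anisotropic spacing in mm.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(const LogicalVector& seeds, const IntegerVector& dims,
                         const NumericVector& spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* o = out.begin();
  const int* s = seeds.begin();
  const double LARGE = 1e20;  // finite sentinel keeps the envelope NaN-free
  for (R_xlen_t q = 0; q < out.size(); ++q) o[q] = s[q] ? 0.0 : LARGE;
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int mx = std::max(nx, std::max(ny, nz));
  std::vector<double> f(mx), d(mx);
  for (int axis = 0; axis < 3; ++axis) {
    const int len = n[axis];
    const R_xlen_t st = stride[axis];
    const int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
    for (int p2 = 0; p2 < n[a2]; ++p2)
      for (int p1 = 0; p1 < n[a1]; ++p1) {
        double* line = o + stride[a1] * p1 + stride[a2] * p2;
        for (int i = 0; i < len; ++i) f[i] = std::min(line[st * i], LARGE);
        dt1d(f, d, len, spacing[axis]);
        for (int i = 0; i < len; ++i) line[st * i] = d[i];
      }
  }
  out.attr("dim") = dims;
  return out;
}

// Symmetric Hausdorff distance between two point sets (rows are points, mm).
// [[Rcpp::export]]
double cpp_hausdorff_points(const NumericMatrix& A, const NumericMatrix& B) {
  const int na = A.nrow(), nb = B.nrow();
  double hmax = 0.0;
  for (int pass = 0; pass < 2; ++pass) {
    const NumericMatrix& P = pass ? B : A;
    const NumericMatrix& Q = pass ? A : B;
    const int np = P.nrow(), nq = Q.nrow();
    for (int a = 0; a < np; ++a) {
      double mn = R_PosInf;
      const double ax = P(a, 0), ay = P(a, 1), az = P(a, 2);
      for (int b = 0; b < nq; ++b) {
        const double dx = ax - Q(b, 0), dy = ay - Q(b, 1), dz = az - Q(b, 2);
        const double d = dx * dx + dy * dy + dz * dz;
        if (d < mn) mn = d;
        if (mn <= hmax * hmax) break;  // cannot raise the running maximum
      }
      if (mn > hmax * hmax && mn < R_PosInf) hmax = std::sqrt(mn);
    }
  }
  (void)na; (void)nb;
  return hmax;
}

// Connected components of a binary mask (26- or 6-connectivity); labels 1..n
// in scan order, 0 elsewhere.
// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector& mask, const IntegerVector& dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t V = (R_xlen_t)nx * ny * nz;
  IntegerVector out(V);
  const int* m = mask.begin();
  int* o = out.begin();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < V; ++seed) {
    if (!m[seed] || o[seed]) continue;
    ++next;
    stack.push_back(seed);
    o[seed] = next;
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) > 1)
              continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            const R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (m[w] && !o[w]) {
              o[w] = next;
              stack.push_back(w);
            }
          }
    }
  }
  out.attr("dim") = dims;
  return out;
}
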
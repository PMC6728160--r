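#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Squared patch difference between target patch at x and atlas patch at y.
// Patches are clipped at grid borders; the sum over the valid offsets is
// rescaled by (full patch size / number of valid offsets) so border patches
// are weighted consistently with interior ones.
static double patch_dist2(const double* f, const double* fn, int nx, int ny, int nz,
                          int xi, int xj, int xk, int yi, int yj, int yk, int pr) {
  double acc = 0.0;
  int nvalid = 0;
  for (int ok = -pr; ok <= pr; ++ok)
    for (int oj = -pr; oj <= pr; ++oj)
      for (int oi = -pr; oi <= pr; ++oi) {
        const int ai = xi + oi, aj = xj + oj, ak = xk + ok;
        const int bi = yi + oi, bj = yj + oj, bk = yk + ok;
        if (ai < 0 || aj < 0 || ak < 0 || ai >= nx || aj >= ny || ak >= nz) continue;
        if (bi < 0 || bj < 0 || bk < 0 || bi >= nx || bj >= ny || bk >= nz) continue;
        const double d = f[ai + (R_xlen_t)nx * (aj + (R_xlen_t)ny * ak)] -
                         fn[bi + (R_xlen_t)nx * (bj + (R_xlen_t)ny * bk)];
        acc += d * d;
        ++nvalid;
      }
  const int full = (2 * pr + 1) * (2 * pr + 1) * (2 * pr + 1);
  return acc * ((double)full / (double)nvalid);
}

// Non-local patch-based label fusion: per voxel x, vote over atlases n and
// window positions y with weight exp(-||f_x - f_{n,y}||^2 / h) for the label
// l_n(y); argmax over classes, ties to the lower class index. When every
// (n, y) pair in the window votes for the same class the weights are
// irrelevant and the unanimous class is returned directly.
// [[Rcpp::export]]
IntegerVector cpp_fuse_labels(const NumericVector& target, const IntegerVector& dims,
                              const List& vols, const List& labs, int K,
                              int pr, int wr, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int L = vols.size();
  std::vector<const double*> fv(L);
  std::vector<const int*> lv(L);
  for (int n = 0; n < L; ++n) {
    NumericVector v = vols[n];
    IntegerVector l = labs[n];
    fv[n] = v.begin();
    lv[n] = l.begin();
  }
  const double* f = target.begin();
  IntegerVector out((R_xlen_t)nx * ny * nz);
  int* o = out.begin();
  std::vector<double> votes(K);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        // unanimity scan
        int first = -1;
        bool unanimous = true;
        for (int n = 0; n < L && unanimous; ++n)
          for (int ok = -wr; ok <= wr && unanimous; ++ok)
            for (int oj = -wr; oj <= wr && unanimous; ++oj)
              for (int oi = -wr; oi <= wr; ++oi) {
                const int yi = i + oi, yj = j + oj, yk = k + ok;
                if (yi < 0 || yj < 0 || yk < 0 || yi >= nx || yj >= ny || yk >= nz)
                  continue;
                const int lab = lv[n][yi + (R_xlen_t)nx * (yj + (R_xlen_t)ny * yk)];
                if (first < 0) first = lab;
                else if (lab != first) { unanimous = false; break; }
              }
        const R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (unanimous) { o[v] = first < 0 ? 0 : first; continue; }
        std::fill(votes.begin(), votes.end(), 0.0);
        for (int n = 0; n < L; ++n)
          for (int ok = -wr; ok <= wr; ++ok)
            for (int oj = -wr; oj <= wr; ++oj)
              for (int oi = -wr; oi <= wr; ++oi) {
                const int yi = i + oi, yj = j + oj, yk = k + ok;
                if (yi < 0 || yj < 0 || yk < 0 || yi >= nx || yj >= ny || yk >= nz)
                  continue;
                const double d2 = patch_dist2(f, fv[n], nx, ny, nz, i, j, k,
                                              yi, yj, yk, pr);
                const int lab = lv[n][yi + (R_xlen_t)nx * (yj + (R_xlen_t)ny * yk)];
                votes[lab] += std::exp(-d2 / h);
              }
        int best = 0;
        for (int c = 1; c < K; ++c)
          if (votes[c] > votes[best]) best = c;
        o[v] = best;
      }
  out.attr("dim") = dims;
  return out;
}

// Mean over voxels of the minimum (over atlases) patch distance at y = x;
// used as a scale-adaptive bandwidth h.
// [[Rcpp::export]]
double cpp_mean_min_patch_dist(const NumericVector& target, const IntegerVector& dims,
                               const List& vols, int pr) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int L = vols.size();
  std::vector<const double*> fv(L);
  for (int n = 0; n < L; ++n) {
    NumericVector v = vols[n];
    fv[n] = v.begin();
  }
  const double* f = target.begin();
  double acc = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double mn = R_PosInf;
        for (int n = 0; n < L; ++n) {
          const double d2 = patch_dist2(f, fv[n], nx, ny, nz, i, j, k, i, j, k, pr);
          mn = std::min(mn, d2);
        }
        acc += mn;
      }
  return acc / ((double)nx * ny * nz);
}
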
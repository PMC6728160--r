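#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

#ifndef FCONE
#define FCONE
#endif

// Tensors are column-major R arrays: X[h + H*(w + W*c)] for shape (H, W, C).
// Convolutions use 'same' zero padding and odd kernel sizes, and are lowered
// to a single dgemm via im2col: column (p + kh*(q + kw*ci)) of the patch
// matrix holds X shifted by the kernel offset (p, q) in channel ci, matching
// the (kh, kw, Cin, Cout) weight layout.

static void im2col(const double* x, int H, int W, int Cin, int kh, int kw,
                   double* col) {
  const int ph = kh / 2, pw = kw / 2;
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + HW * ci;
    for (int q = 0; q < kw; ++q)
      for (int p = 0; p < kh; ++p) {
        double* dst = col + HW * ((R_xlen_t)p + kh * (q + (R_xlen_t)kw * ci));
        const int dh = p - ph, dw = q - pw;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        std::fill(dst, dst + HW, 0.0);
        for (int w2 = w0; w2 < w1; ++w2) {
          const double* srcp = xc + (h0 + dh) + (R_xlen_t)H * (w2 + dw);
          std::copy(srcp, srcp + (h1 - h0), dst + h0 + (R_xlen_t)H * w2);
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(const NumericVector& X, const NumericVector& Wt,
                             const NumericVector& b, int H, int W, int Cin,
                             int Cout, int kh, int kw) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  const int Kc = kh * kw * Cin;
  NumericVector Y(HW * Cout);
  std::vector<double> col((size_t)HW * Kc);
  im2col(X.begin(), H, W, Cin, kh, kw, col.data());
  const int m = (int)HW, n = Cout, k = Kc;
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m, &n, &k, &one, col.data(), &m,
                  Wt.begin(), &k, &zero, Y.begin(), &m FCONE FCONE);
  double* y = Y.begin();
  for (int co = 0; co < Cout; ++co) {
    const double bias = b[co];
    double* yc = y + HW * co;
    for (R_xlen_t i = 0; i < HW; ++i) yc[i] += bias;
  }
  Y.attr("dim") = IntegerVector::create(H, W, Cout);
  return Y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const NumericVector& X, const NumericVector& Wt,
                    const NumericVector& dY, int H, int W, int Cin, int Cout,
                    int kh, int kw) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  const int Kc = kh * kw * Cin;
  const int ph = kh / 2, pw = kw / 2;
  NumericVector dX(HW * Cin);
  NumericVector dW((R_xlen_t)Kc * Cout);
  NumericVector db(Cout);
  std::vector<double> col((size_t)HW * Kc);
  im2col(X.begin(), H, W, Cin, kh, kw, col.data());
  const int m = (int)HW, n = Cout, k = Kc;
  const double one = 1.0, zero = 0.0;
  // dW = t(col) %*% dY
  F77_CALL(dgemm)("T", "N", &k, &n, &m, &one, col.data(), &m,
                  dY.begin(), &m, &zero, dW.begin(), &k FCONE FCONE);
  // dcol = dY %*% t(W), then scatter (col2im) into dX
  std::vector<double> dcol((size_t)HW * Kc);
  F77_CALL(dgemm)("N", "T", &m, &k, &n, &one, dY.begin(), &m,
                  Wt.begin(), &k, &zero, dcol.data(), &m FCONE FCONE);
  double* dx = dX.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    double* dxc = dx + HW * ci;
    for (int q = 0; q < kw; ++q)
      for (int p = 0; p < kh; ++p) {
        const double* src0 = dcol.data() + HW * ((R_xlen_t)p + kh * (q + (R_xlen_t)kw * ci));
        const int dh = p - ph, dw = q - pw;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        for (int w2 = w0; w2 < w1; ++w2) {
          const double* srcp = src0 + h0 + (R_xlen_t)H * w2;
          double* dst = dxc + (h0 + dh) + (R_xlen_t)H * (w2 + dw);
          for (int h = h0; h < h1; ++h) *dst++ += *srcp++;
        }
      }
  }
  const double* dy = dY.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* dyc = dy + HW * co;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < HW; ++i) acc += dyc[i];
    db[co] = acc;
  }
  dX.attr("dim") = IntegerVector::create(H, W, Cin);
  dW.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 2x2 average pooling; H and W must be even.
// [[Rcpp::export]]
NumericVector cpp_avgpool2_fwd(const NumericVector& X, int H, int W, int C) {
  const int H2 = H / 2, W2 = W / 2;
  NumericVector Y((R_xlen_t)H2 * W2 * C);
  const double* x = X.begin();
  double* y = Y.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        const R_xlen_t base = (R_xlen_t)(2 * h) + H * ((R_xlen_t)2 * w + (R_xlen_t)W * c);
        y[h + (R_xlen_t)H2 * (w + (R_xlen_t)W2 * c)] =
            0.25 * (x[base] + x[base + 1] + x[base + H] + x[base + H + 1]);
      }
  Y.attr("dim") = IntegerVector::create(H2, W2, C);
  return Y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(const NumericVector& dY, int H, int W, int C) {
  const int H2 = H / 2, W2 = W / 2;
  NumericVector dX((R_xlen_t)H * W * C);
  const double* dy = dY.begin();
  double* dx = dX.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        const double g = 0.25 * dy[h + (R_xlen_t)H2 * (w + (R_xlen_t)W2 * c)];
        const R_xlen_t base = (R_xlen_t)(2 * h) + H * ((R_xlen_t)2 * w + (R_xlen_t)W * c);
        dx[base] += g; dx[base + 1] += g; dx[base + H] += g; dx[base + H + 1] += g;
      }
  dX.attr("dim") = IntegerVector::create(H, W, C);
  return dX;
}

// Nearest-neighbour upsampling by integer factor f.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(const NumericVector& X, int H, int W, int C, int f) {
  const int H2 = H * f, W2 = W * f;
  NumericVector Y((R_xlen_t)H2 * W2 * C);
  const double* x = X.begin();
  double* y = Y.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h)
        y[h + (R_xlen_t)H2 * (w + (R_xlen_t)W2 * c)] =
            x[(h / f) + (R_xlen_t)H * ((w / f) + (R_xlen_t)W * c)];
  Y.attr("dim") = IntegerVector::create(H2, W2, C);
  return Y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(const NumericVector& dY, int H, int W, int C, int f) {
  const int H2 = H * f, W2 = W * f;
  NumericVector dX((R_xlen_t)H * W * C);
  const double* dy = dY.begin();
  double* dx = dX.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h)
        dx[(h / f) + (R_xlen_t)H * ((w / f) + (R_xlen_t)W * c)] +=
            dy[h + (R_xlen_t)H2 * (w + (R_xlen_t)W2 * c)];
  dX.attr("dim") = IntegerVector::create(H, W, C);
  return dX;
}

static inline void softmax_inplace(double* p, int K) {
  double mx = p[0];
  for (int k = 1; k < K; ++k) mx = std::max(mx, p[k]);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { p[k] = std::exp(p[k] - mx); s += p[k]; }
  for (int k = 0; k < K; ++k) p[k] /= s;
}

// Layout note: head outputs are (H, W, S*K) arrays with the class k of slice s
// stored at channel k + K*s, so per-voxel class values are strided by H*W.
static inline R_xlen_t vox_base(int h, int w, int s, int H, int W, int K) {
  return h + (R_xlen_t)H * (w + (R_xlen_t)W * ((R_xlen_t)K * s));
}

// Global soft Dice loss for one sample: a single quotient over all classes and
// voxels, L = -2*N/D with N = sum_j P[j, t_j] and
// D = sum_{k,j} (1{t_j=k}^2 + P^2 + eps) = V + sum P^2 + V*K*eps.
// truth: 0-based class per voxel, length H*W*S, (H,W,S) order.
// [[Rcpp::export]]
List cpp_seg_dice_loss(const NumericVector& logits, const IntegerVector& truth,
                       int H, int W, int S, int K, double eps, bool want_grad) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t V = HW * S;
  NumericVector prob(clone(logits));
  double* p = prob.begin();
  const int* t = truth.begin();
  std::vector<double> buf(K), dbuf(K);
  double N = 0.0, Psq = 0.0;
  for (int s = 0; s < S; ++s)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const R_xlen_t b = vox_base(h, w, s, H, W, K);
        for (int k = 0; k < K; ++k) buf[k] = p[b + HW * k];
        softmax_inplace(buf.data(), K);
        const int tj = t[h + (R_xlen_t)H * (w + (R_xlen_t)W * s)];
        N += buf[tj];
        for (int k = 0; k < K; ++k) {
          Psq += buf[k] * buf[k];
          p[b + HW * k] = buf[k];
        }
      }
  const double D = (double)V + Psq + (double)V * K * eps;
  const double loss = -2.0 * N / D;
  List out = List::create(_["loss"] = loss, _["prob"] = prob);
  if (want_grad) {
    NumericVector dlog(logits.size());
    double* dl = dlog.begin();
    const double cN = -2.0 / D;              // dL/dN
    const double cD = 2.0 * N / (D * D);     // dL/dD
    for (int s = 0; s < S; ++s)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const R_xlen_t b = vox_base(h, w, s, H, W, K);
          const int tj = t[h + (R_xlen_t)H * (w + (R_xlen_t)W * s)];
          double dot = 0.0;
          for (int k = 0; k < K; ++k) {
            const double pk = p[b + HW * k];
            double dPk = cD * 2.0 * pk;
            if (k == tj) dPk += cN;
            buf[k] = pk;
            dbuf[k] = dPk;
            dot += dPk * pk;
          }
          for (int k = 0; k < K; ++k) dl[b + HW * k] = buf[k] * (dbuf[k] - dot);
        }
    out["dlogits"] = dlog;
  }
  return out;
}

// Per-class soft Dice loss variant: one quotient per class, summed,
// L = -sum_k 2*N_k/D_k with N_k = sum_j 1{t_j=k} P_jk and
// D_k = sum_j (1{t_j=k} + P_jk^2 + eps). Range (-K, 0].
// [[Rcpp::export]]
List cpp_seg_dice_loss_perclass(const NumericVector& logits, const IntegerVector& truth,
                                int H, int W, int S, int K, double eps,
                                bool want_grad) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t V = HW * S;
  NumericVector prob(clone(logits));
  double* p = prob.begin();
  const int* t = truth.begin();
  std::vector<double> buf(K), dbuf(K), Nk(K, 0.0), Dk(K, 0.0);
  for (int k = 0; k < K; ++k) Dk[k] = (double)V * eps;
  for (int s = 0; s < S; ++s)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const R_xlen_t b = vox_base(h, w, s, H, W, K);
        for (int k = 0; k < K; ++k) buf[k] = p[b + HW * k];
        softmax_inplace(buf.data(), K);
        const int tj = t[h + (R_xlen_t)H * (w + (R_xlen_t)W * s)];
        Nk[tj] += buf[tj];
        Dk[tj] += 1.0;
        for (int k = 0; k < K; ++k) {
          Dk[k] += buf[k] * buf[k];
          p[b + HW * k] = buf[k];
        }
      }
  double loss = 0.0;
  for (int k = 0; k < K; ++k) loss -= 2.0 * Nk[k] / Dk[k];
  List out = List::create(_["loss"] = loss, _["prob"] = prob);
  if (want_grad) {
    NumericVector dlog(logits.size());
    double* dl = dlog.begin();
    for (int s = 0; s < S; ++s)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const R_xlen_t b = vox_base(h, w, s, H, W, K);
          const int tj = t[h + (R_xlen_t)H * (w + (R_xlen_t)W * s)];
          double dot = 0.0;
          for (int k = 0; k < K; ++k) {
            const double pk = p[b + HW * k];
            double dPk = 4.0 * Nk[k] / (Dk[k] * Dk[k]) * pk;
            if (k == tj) dPk += -2.0 / Dk[k];
            buf[k] = pk;
            dbuf[k] = dPk;
            dot += dPk * pk;
          }
          for (int k = 0; k < K; ++k) dl[b + HW * k] = buf[k] * (dbuf[k] - dot);
        }
    out["dlogits"] = dlog;
  }
  return out;
}

// Class-balanced weighted categorical cross-entropy for landmarks:
// L = -sum_k w_k sum_{j in Y_k} log P[j,k]; probabilities clamped from below.
// [[Rcpp::export]]
List cpp_lm_ce_loss(const NumericVector& logits, const IntegerVector& truth,
                    int H, int W, int S, int K, const NumericVector& wts,
                    double clamp, bool want_grad) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector prob(clone(logits));
  double* p = prob.begin();
  const int* t = truth.begin();
  std::vector<double> buf(K);
  double loss = 0.0;
  for (int s = 0; s < S; ++s)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const R_xlen_t b = vox_base(h, w, s, H, W, K);
        for (int k = 0; k < K; ++k) buf[k] = p[b + HW * k];
        softmax_inplace(buf.data(), K);
        const int tj = t[h + (R_xlen_t)H * (w + (R_xlen_t)W * s)];
        loss -= wts[tj] * std::log(std::max(buf[tj], clamp));
        for (int k = 0; k < K; ++k) p[b + HW * k] = buf[k];
      }
  List out = List::create(_["loss"] = loss, _["prob"] = prob);
  if (want_grad) {
    NumericVector dlog(logits.size());
    double* dl = dlog.begin();
    for (int s = 0; s < S; ++s)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const R_xlen_t b = vox_base(h, w, s, H, W, K);
          const int tj = t[h + (R_xlen_t)H * (w + (R_xlen_t)W * s)];
          const double wgt = wts[tj];
          for (int k = 0; k < K; ++k)
            dl[b + HW * k] = wgt * (p[b + HW * k] - (k == tj ? 1.0 : 0.0));
        }
    out["dlogits"] = dlog;
  }
  return out;
}
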
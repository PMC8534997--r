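// Hot loops of the CNN engine: patch extraction (im2col) and its adjoint
// (col2im) for strided "same" convolutions on channels-first activations,
// plus fused batch-normalization(+ReLU) passes. Everything else (matrix
// products, optimizer) stays in R on top of BLAS.

#include <Rcpp.h>
using namespace Rcpp;

// x: (cin x h*w*b), columns indexed by (y, x, batch), y fastest.
// Returns P: (k*k*cin x oh*ow*b); column blocks of width cin correspond to
// kernel offsets in column-major (dy, dx) order, matching the weight layout.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int h, int w, int b,
                         int ksize, int stride, int pt, int pl) {
  const int cin = x.nrow();
  const int oh = (h + stride - 1) / stride;
  const int ow = (w + stride - 1) / stride;
  NumericMatrix P(ksize * ksize * cin, oh * ow * b);
  const double* xp = x.begin();
  double* pp = P.begin();
  const int prow = P.nrow();
  for (int bb = 0; bb < b; ++bb) {
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        const R_xlen_t pcol = (R_xlen_t)oy + (R_xlen_t)oh * ox +
                              (R_xlen_t)oh * ow * bb;
        double* pcolp = pp + pcol * prow;
        for (int kj = 0; kj < ksize; ++kj) {
          const int ix = ox * stride + kj - pl;
          for (int ki = 0; ki < ksize; ++ki) {
            const int iy = oy * stride + ki - pt;
            const int kidx = kj * ksize + ki;
            double* dst = pcolp + (R_xlen_t)kidx * cin;
            if (ix >= 0 && ix < w && iy >= 0 && iy < h) {
              const double* src = xp +
                ((R_xlen_t)iy + (R_xlen_t)h * ix + (R_xlen_t)h * w * bb) * cin;
              for (int c = 0; c < cin; ++c) dst[c] = src[c];
            }
            // P is zero-initialized; padding positions stay zero
          }
        }
      }
    }
  }
  return P;
}

// Adjoint of cpp_im2col: scatter-adds patch gradients back to the input.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dP, int h, int w, int b,
                         int ksize, int stride, int pt, int pl) {
  const int cin = dP.nrow() / (ksize * ksize);
  const int oh = (h + stride - 1) / stride;
  const int ow = (w + stride - 1) / stride;
  NumericMatrix dX(cin, (R_xlen_t)h * w * b);
  const double* dpp = dP.begin();
  double* dxp = dX.begin();
  const int prow = dP.nrow();
  for (int bb = 0; bb < b; ++bb) {
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        const R_xlen_t pcol = (R_xlen_t)oy + (R_xlen_t)oh * ox +
                              (R_xlen_t)oh * ow * bb;
        const double* pcolp = dpp + pcol * prow;
        for (int kj = 0; kj < ksize; ++kj) {
          const int ix = ox * stride + kj - pl;
          if (ix < 0 || ix >= w) continue;
          for (int ki = 0; ki < ksize; ++ki) {
            const int iy = oy * stride + ki - pt;
            if (iy < 0 || iy >= h) continue;
            const int kidx = kj * ksize + ki;
            const double* src = pcolp + (R_xlen_t)kidx * cin;
            double* dst = dxp +
              ((R_xlen_t)iy + (R_xlen_t)h * ix + (R_xlen_t)h * w * bb) * cin;
            for (int c = 0; c < cin; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return dX;
}

// Fused batch-norm (+ optional ReLU) training forward on a (channels x n)
// activation matrix: returns the activated output, the standardized
// activations (kept for the backward pass), and per-channel batch
// mean / biased variance.
// [[Rcpp::export]]
List cpp_bn_forward(const NumericMatrix& M, const NumericVector& gamma,
                    const NumericVector& beta, double eps, bool relu) {
  const int c = M.nrow();
  const R_xlen_t n = M.ncol();
  NumericVector mu(c), va(c), istd(c);
  const double* mp = M.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* col = mp + j * c;
    for (int i = 0; i < c; ++i) { mu[i] += col[i]; va[i] += col[i] * col[i]; }
  }
  for (int i = 0; i < c; ++i) {
    mu[i] /= n;
    va[i] = va[i] / n - mu[i] * mu[i];
    istd[i] = 1.0 / std::sqrt(va[i] + eps);
  }
  NumericMatrix Y(c, n), xhat(c, n);
  double* yp = Y.begin(); double* xp = xhat.begin();
  const double* gp = gamma.begin(); const double* bp = beta.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* col = mp + j * c;
    double* yc = yp + j * c; double* xc = xp + j * c;
    for (int i = 0; i < c; ++i) {
      const double z = (col[i] - mu[i]) * istd[i];
      xc[i] = z;
      double y = z * gp[i] + bp[i];
      if (relu && y < 0) y = 0;
      yc[i] = y;
    }
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["istd"] = istd,
                      _["mu"] = mu, _["va"] = va);
}

// Fused batch-norm (+ ReLU) training backward. When relu is set, the
// incoming gradient is first masked by the activation's support, which is
// recomputed from xhat (y = xhat * gamma + beta > 0) instead of storing a
// mask.
// [[Rcpp::export]]
List cpp_bn_backward(const NumericMatrix& dY, const NumericMatrix& xhat,
                     const NumericVector& istd, const NumericVector& gamma,
                     const NumericVector& beta, bool relu) {
  const int c = dY.nrow();
  const R_xlen_t n = dY.ncol();
  NumericVector dgamma(c), dbeta(c);
  const double* dp = dY.begin();
  const double* xp = xhat.begin();
  const double* gp = gamma.begin(); const double* bp = beta.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* dc = dp + j * c; const double* xc = xp + j * c;
    for (int i = 0; i < c; ++i) {
      double d = dc[i];
      if (relu && xc[i] * gp[i] + bp[i] <= 0) d = 0;
      dgamma[i] += d * xc[i];
      dbeta[i] += d;
    }
  }
  NumericMatrix dX(c, n);
  double* op = dX.begin();
  // dX = istd * gamma * (dY - mean(dY) - xhat * mean(dY * xhat))
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* dc = dp + j * c; const double* xc = xp + j * c;
    double* oc = op + j * c;
    for (int i = 0; i < c; ++i) {
      double d = dc[i];
      if (relu && xc[i] * gp[i] + bp[i] <= 0) d = 0;
      oc[i] = istd[i] * gamma[i] *
        (d - dbeta[i] / n - xc[i] * dgamma[i] / n);
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Batch-norm inference: affine transform with the moving statistics folded
// into per-channel scale/shift, plus optional ReLU.
// [[Rcpp::export]]
NumericMatrix cpp_bn_infer(const NumericMatrix& M, const NumericVector& scale,
                           const NumericVector& shift, bool relu) {
  const int c = M.nrow();
  const R_xlen_t n = M.ncol();
  NumericMatrix Y(c, n);
  const double* mp = M.begin();
  double* yp = Y.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* col = mp + j * c;
    double* yc = yp + j * c;
    for (int i = 0; i < c; ++i) {
      double y = col[i] * scale[i] + shift[i];
      if (relu && y < 0) y = 0;
      yc[i] = y;
    }
  }
  return Y;
}
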
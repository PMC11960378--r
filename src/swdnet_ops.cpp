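// Numerical kernels: cascaded biquad filtering and 2-D convolution
// (im2col + BLAS GEMM) with its gradient. Layout conventions match the R
// side: signal tensors are column-major (H, W, C, B) arrays, kernels are
// (kh, kw, Cin, Cout). "Same" zero padding, stride 1, odd kernel sizes.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector sosfilt_run(const NumericMatrix& sos, const NumericVector& x,
                          const NumericMatrix& zi) {
  const int ns = sos.nrow();
  const int n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z0 = zi(s, 0), z1 = zi(s, 1);
    double* yp = REAL(y);
    for (int t = 0; t < n; ++t) {
      const double xt = yp[t];
      const double yt = b0 * xt + z0;
      z0 = b1 * xt - a1 * yt + z1;
      z1 = b2 * xt - a2 * yt;
      yp[t] = yt;
    }
  }
  return y;
}

static void im2col(const double* x, int H, int W, int C, int kh, int kw,
                   int pad_h, int pad_w, arma::mat& cols) {
  // cols: (H*W) x (kh*kw*C); zero-fill only the padded border entries
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        double* dst = cols.colptr(q);
        const int i_lo = std::max(0, pad_h - ki);
        const int i_hi = std::min(H, H + pad_h - ki);
        for (int j = 0; j < W; ++j) {
          const int j2 = j + kj - pad_w;
          double* dj = dst + (size_t)H * j;
          if (j2 < 0 || j2 >= W) {
            std::memset(dj, 0, (size_t)H * sizeof(double));
            continue;
          }
          const double* src = x + (size_t)H * (j2 + (size_t)W * c);
          if (i_lo > 0) std::memset(dj, 0, (size_t)i_lo * sizeof(double));
          if (i_hi > i_lo) {
            std::memcpy(dj + i_lo, src + i_lo + ki - pad_h,
                        (size_t)(i_hi - i_lo) * sizeof(double));
          }
          if (i_hi < H) {
            std::memset(dj + i_hi, 0, (size_t)(H - i_hi) * sizeof(double));
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C, int kh, int kw,
                   int pad_h, int pad_w, double* dx) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        const double* src = cols.colptr(q);
        for (int j = 0; j < W; ++j) {
          const int j2 = j + kj - pad_w;
          if (j2 < 0 || j2 >= W) continue;
          double* dst = dx + (size_t)H * (j2 + (size_t)W * c);
          const int i_lo = std::max(0, pad_h - ki);
          const int i_hi = std::min(H, H + pad_h - ki);
          for (int i = i_lo; i < i_hi; ++i) {
            dst[i + ki - pad_h] += src[i + (size_t)H * j];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(const NumericVector& x, const NumericVector& w,
                        const NumericVector& bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d_fw: channel mismatch");
  const int pad_h = (kh - 1) / 2, pad_w = (kw - 1) / 2;
  const int K = kh * kw * C;
  NumericVector out((R_xlen_t)H * W * Cout * B);
  out.attr("dim") = IntegerVector::create(H, W, Cout, B);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat cols((size_t)H * W, K);
  const bool use_bias = bias.size() > 0;
  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (size_t)H * W * C * b;
    im2col(xb, H, W, C, kh, kw, pad_h, pad_w, cols);
    arma::mat Y(out.begin() + (size_t)H * W * Cout * b, (size_t)H * W, Cout,
                false, true);
    Y = cols * Wm;
    if (use_bias) {
      for (int c = 0; c < Cout; ++c) Y.col(c) += bias[c];
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bw(const NumericVector& x, const NumericVector& w,
               const NumericVector& dy, const bool use_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int pad_h = (kh - 1) / 2, pad_w = (kw - 1) / 2;
  const int K = kh * kw * C;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericVector dw((R_xlen_t)kh * kw * C * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat cols((size_t)H * W, K);
  arma::mat dcols((size_t)H * W, K);
  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (size_t)H * W * C * b;
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)H * W * Cout * b,
                 (size_t)H * W, Cout, false, true);
    im2col(xb, H, W, C, kh, kw, pad_h, pad_w, cols);
    dWm += cols.t() * dY;
    if (use_bias) dbv += arma::sum(dY, 0).t();
    dcols = dY * Wm.t();
    col2im(dcols, H, W, C, kh, kw, pad_h, pad_w,
           dx.begin() + (size_t)H * W * C * b);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// per-channel reductions and affine maps for batch normalization on
// (H, W, C, B) tensors: one pass, no R-level tiling

// [[Rcpp::export]]
List chan_dot(const NumericVector& x, const NumericVector& y) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], B = xd[3];
  NumericVector s1(C), s2(C);
  const bool with_y = y.size() == x.size();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + HW * (c + (size_t)C * b);
      double a1 = 0.0, a2 = 0.0;
      if (with_y) {
        const double* yp = y.begin() + HW * (c + (size_t)C * b);
        for (size_t i = 0; i < HW; ++i) { a1 += xp[i]; a2 += xp[i] * yp[i]; }
      } else {
        for (size_t i = 0; i < HW; ++i) { a1 += xp[i]; a2 += xp[i] * xp[i]; }
      }
      s1[c] += a1; s2[c] += a2;
    }
  }
  return List::create(_["s1"] = s1, _["s2"] = s2);
}

// [[Rcpp::export]]
NumericVector chan_affine(const NumericVector& x, const NumericVector& a,
                          const NumericVector& b) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], B = xd[3];
  NumericVector out(x.size());
  out.attr("dim") = xd;
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + HW * (c + (size_t)C * bb);
      double* op = out.begin() + HW * (c + (size_t)C * bb);
      const double ac = a[c], bc = b[c];
      for (size_t i = 0; i < HW; ++i) op[i] = ac * xp[i] + bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector chan_affine2(const NumericVector& x, const NumericVector& y,
                           const NumericVector& a, const NumericVector& b,
                           const NumericVector& cc) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], B = xd[3];
  NumericVector out(x.size());
  out.attr("dim") = xd;
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + HW * (c + (size_t)C * bb);
      const double* yp = y.begin() + HW * (c + (size_t)C * bb);
      double* op = out.begin() + HW * (c + (size_t)C * bb);
      const double ac = a[c], bc = b[c], ccc = cc[c];
      for (size_t i = 0; i < HW; ++i) op[i] = ac * xp[i] + bc * yp[i] + ccc;
    }
  }
  return out;
}
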
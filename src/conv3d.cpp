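// Direct 3D convolution kernels (forward, input-gradient, weight-gradient)
// plus transpose convolution with kernel == stride.
//
// Array layout convention (column-major, matching R): volumes are
// (H, W, D, C) so linear index = h + H*(w + W*(d + D*c)).
// Convolution weights are (k, k, k, Cin, Cout); "same" padding (k-1)/2.
// Batch size is always 1 (the training protocol uses batch 1).
//
// At the narrow channel widths this package trains at (8-32 channels),
// im2col+GEMM runs far below peak because the GEMM is extremely skinny;
// a direct loop with a contiguous H-axis inner loop and a 4-wide
// output-channel block vectorizes well and is considerably faster.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

inline int out_dim(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// forward accumulation for one (ow, od) column over a block of <=4 output
// channels: acc[cb][oh]
template <int CB>
void fwd_col(const double* x, const double* w,
             int H, int W, int D, int cin, int k, int pad, int stride,
             int Ho, int ow, int od, int co0, int cout,
             std::vector<double>& accbuf) {
  double* acc[CB];
  for (int c = 0; c < CB; ++c) {
    acc[c] = accbuf.data() + c * Ho;
    std::fill(acc[c], acc[c] + Ho, 0.0);
  }
  const long planeHW = (long)H * W;
  const long volX = planeHW * D;
  const long k3 = (long)k * k * k;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + ci * volX;
    for (int kd = 0; kd < k; ++kd) {
      const int id = od * stride - pad + kd;
      if (id < 0 || id >= D) continue;
      for (int kw = 0; kw < k; ++kw) {
        const int iw = ow * stride - pad + kw;
        if (iw < 0 || iw >= W) continue;
        const double* xrow = xc + (long)H * iw + planeHW * id;
        const double* wbase = w + k * ((long)kw + k * kd) + k3 * ci;
        for (int kh = 0; kh < k; ++kh) {
          const int sh = kh - pad;            // ih = oh*stride + sh
          // valid oh range: 0 <= oh*stride + sh < H
          int lo = 0, hi = Ho;
          if (stride == 1) {
            lo = std::max(0, -sh);
            hi = std::min(Ho, H - sh);
          } else {
            lo = (sh < 0) ? (( -sh + stride - 1) / stride) : 0;
            hi = std::min(Ho, (H - sh + stride - 1) / stride);
          }
          if (lo >= hi) continue;
          double wv[CB];
          for (int c = 0; c < CB; ++c)
            wv[c] = wbase[kh + k3 * (long)cin * (co0 + c)];
          if (stride == 1) {
            const double* __restrict xs = xrow + sh;
            if (CB == 4) {
              double* __restrict a0 = acc[0];
              double* __restrict a1 = acc[1];
              double* __restrict a2 = acc[2];
              double* __restrict a3 = acc[3];
              const double w0 = wv[0], w1 = wv[1], w2 = wv[2], w3 = wv[3];
              for (int oh = lo; oh < hi; ++oh) {
                const double xv = xs[oh];
                a0[oh] += w0 * xv;
                a1[oh] += w1 * xv;
                a2[oh] += w2 * xv;
                a3[oh] += w3 * xv;
              }
            } else {
              for (int c = 0; c < CB; ++c) {
                double* __restrict a = acc[c];
                const double wc = wv[c];
                for (int oh = lo; oh < hi; ++oh) a[oh] += wc * xs[oh];
              }
            }
          } else {
            for (int c = 0; c < CB; ++c) {
              double* __restrict a = acc[c];
              const double wc = wv[c];
              for (int oh = lo; oh < hi; ++oh)
                a[oh] += wc * xrow[oh * stride + sh];
            }
          }
        }
      }
    }
  }
}

// Fast path for stride 1 and small odd kernels: the H-axis inner loop is a
// K-tap correlation against a zero-padded row buffer, so every accumulator
// store amortizes K*CB fused multiply-adds.
template <int K, int CB, int S>
void fwd_col_fast(const double* x, const double* w,
                  int H, int W, int D, int cin, int pad,
                  int Ho, int ow, int od, int co0,
                  std::vector<double>& accbuf, std::vector<double>& xbuf) {
  double* __restrict a0 = accbuf.data();
  double* __restrict a1 = accbuf.data() + (CB > 1 ? Ho : 0);
  double* __restrict a2 = accbuf.data() + (CB > 2 ? 2 * Ho : 0);
  double* __restrict a3 = accbuf.data() + (CB > 3 ? 3 * Ho : 0);
  std::fill(accbuf.begin(), accbuf.begin() + CB * Ho, 0.0);
  const long planeHW = (long)H * W;
  const long volX = planeHW * D;
  const long k3 = (long)K * K * K;
  double* __restrict xb = xbuf.data();
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + ci * volX;
    for (int kd = 0; kd < K; ++kd) {
      const int id = od * S - pad + kd;
      if (id < 0 || id >= D) continue;
      for (int kw = 0; kw < K; ++kw) {
        const int iw = ow * S - pad + kw;
        if (iw < 0 || iw >= W) continue;
        const double* __restrict xrow = xc + (long)H * iw + planeHW * id;
        for (int t = 0; t < pad; ++t) { xb[t] = 0.0; xb[H + pad + t] = 0.0; }
        for (int t = 0; t < H; ++t) xb[pad + t] = xrow[t];
        const double* wbase = w + K * ((long)kw + K * kd) + k3 * ci;
        const long wstride = k3 * (long)cin;
        const double* w0 = wbase + wstride * co0;
        const double* w1 = (CB > 1) ? wbase + wstride * (co0 + 1) : w0;
        const double* w2 = (CB > 2) ? wbase + wstride * (co0 + 2) : w0;
        const double* w3 = (CB > 3) ? wbase + wstride * (co0 + 3) : w0;
        if (K == 5) {
          const double c00 = w0[0], c01 = w0[1], c02 = w0[2], c03 = w0[3], c04 = w0[4];
          const double c10 = w1[0], c11 = w1[1], c12 = w1[2], c13 = w1[3], c14 = w1[4];
          const double c20 = w2[0], c21 = w2[1], c22 = w2[2], c23 = w2[3], c24 = w2[4];
          const double c30 = w3[0], c31 = w3[1], c32 = w3[2], c33 = w3[3], c34 = w3[4];
          for (int oh = 0; oh < Ho; ++oh) {
            const double x0 = xb[S * oh], x1 = xb[S * oh + 1], x2 = xb[S * oh + 2],
                         x3 = xb[S * oh + 3], x4 = xb[S * oh + 4];
            a0[oh] += (c00 * x0 + c01 * x1) + (c02 * x2 + c03 * x3) + c04 * x4;
            if (CB > 1)
              a1[oh] += (c10 * x0 + c11 * x1) + (c12 * x2 + c13 * x3) + c14 * x4;
            if (CB > 2)
              a2[oh] += (c20 * x0 + c21 * x1) + (c22 * x2 + c23 * x3) + c24 * x4;
            if (CB > 3)
              a3[oh] += (c30 * x0 + c31 * x1) + (c32 * x2 + c33 * x3) + c34 * x4;
          }
        } else {
          const double c00 = w0[0], c01 = w0[1], c02 = w0[2];
          const double c10 = w1[0], c11 = w1[1], c12 = w1[2];
          const double c20 = w2[0], c21 = w2[1], c22 = w2[2];
          const double c30 = w3[0], c31 = w3[1], c32 = w3[2];
          for (int oh = 0; oh < Ho; ++oh) {
            const double x0 = xb[S * oh], x1 = xb[S * oh + 1], x2 = xb[S * oh + 2];
            a0[oh] += (c00 * x0 + c01 * x1) + c02 * x2;
            if (CB > 1) a1[oh] += (c10 * x0 + c11 * x1) + c12 * x2;
            if (CB > 2) a2[oh] += (c20 * x0 + c21 * x1) + c22 * x2;
            if (CB > 3) a3[oh] += (c30 * x0 + c31 * x1) + c32 * x2;
          }
        }
      }
    }
  }
}

// Fast stride-1 backward for one (ow, od, ci, kd, kw) tap group over a
// block of CB output channels: dx row gains K-tap correlations of the
// padded dy rows with the flipped kernels (one store per K*CB FMAs); dw
// gains K dot products per channel with register accumulators.
// dyrows/wtaps/dwtaps: per-channel pointers; dybuf holds CB padded rows.
template <int K, int CB>
void bwd_rows_fast(const double* __restrict xrow, double* __restrict dxrow,
                   const double* const* dyrows, const double* const* wtaps,
                   double* const* dwtaps, int H, int pad,
                   std::vector<double>& dybuf, std::vector<double>& xbuf) {
  const int L = H + 2 * pad;
  double* __restrict xb = xbuf.data();
  for (int t = 0; t < pad; ++t) { xb[t] = 0.0; xb[H + pad + t] = 0.0; }
  for (int t = 0; t < H; ++t) xb[pad + t] = xrow[t];
  for (int c = 0; c < CB; ++c) {
    double* db = dybuf.data() + c * L;
    for (int t = 0; t < pad; ++t) { db[t] = 0.0; db[H + pad + t] = 0.0; }
    const double* dyr = dyrows[c];
    for (int t = 0; t < H; ++t) db[pad + t] = dyr[t];
  }
  const double* __restrict db0 = dybuf.data();
  const double* __restrict db1 = dybuf.data() + (CB > 1 ? L : 0);
  const double* __restrict db2 = dybuf.data() + (CB > 2 ? 2 * L : 0);
  const double* __restrict db3 = dybuf.data() + (CB > 3 ? 3 * L : 0);
  double w[CB][K];
  for (int c = 0; c < CB; ++c)
    for (int kh = 0; kh < K; ++kh) w[c][kh] = wtaps[c][kh];
  for (int ih = 0; ih < H; ++ih) {
    double s = 0;
    for (int kh = 0; kh < K; ++kh) {
      const int off = ih + K - 1 - kh;
      s += w[0][kh] * db0[off];
      if (CB > 1) s += w[1][kh] * db1[off];
      if (CB > 2) s += w[2][kh] * db2[off];
      if (CB > 3) s += w[3][kh] * db3[off];
    }
    dxrow[ih] += s;
  }
  for (int c = 0; c < CB; ++c) {
    const double* __restrict db = dybuf.data() + c * L;
    double aw[K];
    for (int kh = 0; kh < K; ++kh) aw[kh] = 0.0;
    for (int oh = 0; oh < H; ++oh) {
      const double g = db[pad + oh];
      const double* __restrict xs = xb + oh;
      for (int kh = 0; kh < K; ++kh) aw[kh] += xs[kh] * g;
    }
    for (int kh = 0; kh < K; ++kh) dwtaps[c][kh] += aw[kh];
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_conv3d_forward")]]
NumericVector cpp_conv3d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, NumericVector bias,
                                 int k, int cin, int cout,
                                 int stride, int pad) {
  const int H = xdim[0], W = xdim[1], D = xdim[2];
  if (k == 1 && stride == 1) {
    // pointwise convolution is a plain GEMM
    const long N = (long)H * W * D;
    arma::mat Xm(const_cast<double*>(x.begin()), N, cin, false, true);
    arma::mat Wm(const_cast<double*>(w.begin()), cin, cout, false, true);
    NumericVector y(N * cout);
    arma::mat Ym(y.begin(), N, cout, false, true);
    Ym = Xm * Wm;
    if (bias.size() == (R_xlen_t)cout)
      for (int co = 0; co < cout; ++co) Ym.col(co) += bias[co];
    y.attr("dim") = IntegerVector::create(H, W, D, cout);
    return y;
  }
  const int Ho = out_dim(H, k, pad, stride);
  const int Wo = out_dim(W, k, pad, stride);
  const int Do = out_dim(D, k, pad, stride);
  NumericVector y((long)Ho * Wo * Do * cout);
  const long planeO = (long)Ho * Wo;
  const long volO = planeO * Do;
  const bool has_bias = bias.size() == (R_xlen_t)cout;
  std::vector<double> accbuf(4 * Ho);
  std::vector<double> xbuf(H + 2 * pad + 1);
  const bool fast = (stride <= 2) && (k == 3 || k == 5);
  double* yp = y.begin();
  for (int od = 0; od < Do; ++od) {
    for (int ow = 0; ow < Wo; ++ow) {
      int co = 0;
      for (; co + 4 <= cout; co += 4) {
        if (fast && k == 5 && stride == 1)
          fwd_col_fast<5, 4, 1>(x.begin(), w.begin(), H, W, D, cin, pad,
                                Ho, ow, od, co, accbuf, xbuf);
        else if (fast && k == 3 && stride == 1)
          fwd_col_fast<3, 4, 1>(x.begin(), w.begin(), H, W, D, cin, pad,
                                Ho, ow, od, co, accbuf, xbuf);
        else if (fast && k == 5)
          fwd_col_fast<5, 4, 2>(x.begin(), w.begin(), H, W, D, cin, pad,
                                Ho, ow, od, co, accbuf, xbuf);
        else if (fast)
          fwd_col_fast<3, 4, 2>(x.begin(), w.begin(), H, W, D, cin, pad,
                                Ho, ow, od, co, accbuf, xbuf);
        else
          fwd_col<4>(x.begin(), w.begin(), H, W, D, cin, k, pad, stride,
                     Ho, ow, od, co, cout, accbuf);
        for (int c = 0; c < 4; ++c) {
          double* dst = yp + (long)Ho * ow + planeO * od + volO * (co + c);
          const double b = has_bias ? bias[co + c] : 0.0;
          const double* a = accbuf.data() + c * Ho;
          for (int oh = 0; oh < Ho; ++oh) dst[oh] = a[oh] + b;
        }
      }
      for (; co < cout; ++co) {
        if (fast && k == 5 && stride == 1)
          fwd_col_fast<5, 1, 1>(x.begin(), w.begin(), H, W, D, cin, pad,
                                Ho, ow, od, co, accbuf, xbuf);
        else if (fast && k == 3 && stride == 1)
          fwd_col_fast<3, 1, 1>(x.begin(), w.begin(), H, W, D, cin, pad,
                                Ho, ow, od, co, accbuf, xbuf);
        else if (fast && k == 5)
          fwd_col_fast<5, 1, 2>(x.begin(), w.begin(), H, W, D, cin, pad,
                                Ho, ow, od, co, accbuf, xbuf);
        else if (fast && k == 3)
          fwd_col_fast<3, 1, 2>(x.begin(), w.begin(), H, W, D, cin, pad,
                                Ho, ow, od, co, accbuf, xbuf);
        else
          fwd_col<1>(x.begin(), w.begin(), H, W, D, cin, k, pad, stride,
                     Ho, ow, od, co, cout, accbuf);
        double* dst = yp + (long)Ho * ow + planeO * od + volO * co;
        const double b = has_bias ? bias[co] : 0.0;
        for (int oh = 0; oh < Ho; ++oh) dst[oh] = accbuf[oh] + b;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Do, cout);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv3d_backward")]]
List cpp_conv3d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, NumericVector dy,
                         int k, int cin, int cout,
                         int stride, int pad) {
  const int H = xdim[0], W = xdim[1], D = xdim[2];
  if (k == 1 && stride == 1) {
    const long N = (long)H * W * D;
    arma::mat Xm(const_cast<double*>(x.begin()), N, cin, false, true);
    arma::mat Wm(const_cast<double*>(w.begin()), cin, cout, false, true);
    arma::mat dYm(const_cast<double*>(dy.begin()), N, cout, false, true);
    NumericVector dx(N * cin);
    arma::mat dXm(dx.begin(), N, cin, false, true);
    dXm = dYm * Wm.t();
    arma::mat dWm = Xm.t() * dYm;
    NumericVector dwv(dWm.begin(), dWm.end());
    dwv.attr("dim") = IntegerVector::create(1, 1, 1, cin, cout);
    arma::vec db = arma::sum(dYm, 0).t();
    NumericVector dbv(db.begin(), db.end());
    dx.attr("dim") = IntegerVector::create(H, W, D, cin);
    return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
  }
  const int Ho = out_dim(H, k, pad, stride);
  const int Wo = out_dim(W, k, pad, stride);
  const int Do = out_dim(D, k, pad, stride);
  const long planeHW = (long)H * W, volX = planeHW * D;
  const long planeO = (long)Ho * Wo, volO = planeO * Do;
  const long k3 = (long)k * k * k;

  NumericVector dx((long)H * W * D * cin);
  NumericVector dw((long)k3 * cin * cout);
  NumericVector db(cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();

  for (int co = 0; co < cout; ++co) {
    const double* dyc = dyp + volO * co;
    double acc_b = 0.0;
    for (long i = 0; i < volO; ++i) acc_b += dyc[i];
    db[co] = acc_b;
  }

  std::vector<double> dybuf(4 * (std::max(H, Ho) + 2 * pad));
  std::vector<double> xbuf(H + 2 * pad);
  const bool fast = (stride == 1) && (k == 3 || k == 5);
  for (int od = 0; od < Do; ++od) {
    for (int ow = 0; ow < Wo; ++ow) {
      if (fast) {
        // output-channel blocks of up to 4 share the padded-row buffers
        for (int co0 = 0; co0 < cout; co0 += 4) {
          const int cb = std::min(4, cout - co0);
          const double* dyrows[4]; const double* wtaps[4]; double* dwtaps[4];
          for (int ci = 0; ci < cin; ++ci) {
            const double* xc = xp + ci * volX;
            double* dxc = dxp + ci * volX;
            for (int kd = 0; kd < k; ++kd) {
              const int id = od - pad + kd;
              if (id < 0 || id >= D) continue;
              for (int kw = 0; kw < k; ++kw) {
                const int iw = ow - pad + kw;
                if (iw < 0 || iw >= W) continue;
                const double* xrow = xc + (long)H * iw + planeHW * id;
                double* dxrow = dxc + (long)H * iw + planeHW * id;
                for (int c = 0; c < cb; ++c) {
                  dyrows[c] = dyp + (long)Ho * ow + planeO * od +
                              volO * (co0 + c);
                  const long wb = k * ((long)kw + k * kd) +
                                  k3 * (ci + (long)cin * (co0 + c));
                  wtaps[c] = wp + wb;
                  dwtaps[c] = dwp + wb;
                }
                if (k == 5) {
                  if (cb == 4)
                    bwd_rows_fast<5, 4>(xrow, dxrow, dyrows, wtaps, dwtaps,
                                        H, pad, dybuf, xbuf);
                  else for (int c = 0; c < cb; ++c)
                    bwd_rows_fast<5, 1>(xrow, dxrow, dyrows + c, wtaps + c,
                                        dwtaps + c, H, pad, dybuf, xbuf);
                } else {
                  if (cb == 4)
                    bwd_rows_fast<3, 4>(xrow, dxrow, dyrows, wtaps, dwtaps,
                                        H, pad, dybuf, xbuf);
                  else for (int c = 0; c < cb; ++c)
                    bwd_rows_fast<3, 1>(xrow, dxrow, dyrows + c, wtaps + c,
                                        dwtaps + c, H, pad, dybuf, xbuf);
                }
              }
            }
          }
        }
        continue;
      }
      for (int co = 0; co < cout; ++co) {
        const double* dyrow = dyp + (long)Ho * ow + planeO * od + volO * co;
        for (int ci = 0; ci < cin; ++ci) {
          const double* xc = xp + ci * volX;
          double* dxc = dxp + ci * volX;
          for (int kd = 0; kd < k; ++kd) {
            const int id = od * stride - pad + kd;
            if (id < 0 || id >= D) continue;
            for (int kw = 0; kw < k; ++kw) {
              const int iw = ow * stride - pad + kw;
              if (iw < 0 || iw >= W) continue;
              const double* xrow = xc + (long)H * iw + planeHW * id;
              double* dxrow = dxc + (long)H * iw + planeHW * id;
              const long wb = k * ((long)kw + k * kd) + k3 * (ci + (long)cin * co);
              for (int kh = 0; kh < k; ++kh) {
                const int sh = kh - pad;
                int lo, hi;
                if (stride == 1) {
                  lo = std::max(0, -sh);
                  hi = std::min(Ho, H - sh);
                } else {
                  lo = (sh < 0) ? ((-sh + stride - 1) / stride) : 0;
                  hi = std::min(Ho, (H - sh + stride - 1) / stride);
                }
                if (lo >= hi) continue;
                const double wv = wp[wb + kh];
                double accw = 0.0;
                if (stride == 1) {
                  const double* xs = xrow + sh;
                  double* dxs = dxrow + sh;
                  for (int oh = lo; oh < hi; ++oh) {
                    const double g = dyrow[oh];
                    dxs[oh] += wv * g;
                    accw += xs[oh] * g;
                  }
                } else {
                  for (int oh = lo; oh < hi; ++oh) {
                    const double g = dyrow[oh];
                    dxrow[oh * stride + sh] += wv * g;
                    accw += xrow[oh * stride + sh] * g;
                  }
                }
                dwp[wb + kh] += accw;
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, D, cin);
  dw.attr("dim") = IntegerVector::create(k, k, k, cin, cout);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transpose convolution with kernel == stride (non-overlapping blocks):
// y[s*h + a, s*w + b, s*d + c, co] = sum_ci x[h,w,d,ci] * w[a,b,c,ci,co].
// Weights laid out (s, s, s, Cin, Cout).

// [[Rcpp::export(name = ".cpp_convT3d_forward")]]
NumericVector cpp_convT3d_forward(NumericVector x, IntegerVector xdim,
                                  NumericVector w, NumericVector bias,
                                  int s, int cin, int cout) {
  const int H = xdim[0], W = xdim[1], D = xdim[2];
  const int Ho = H * s, Wo = W * s, Do = D * s;
  const long N = (long)H * W * D;
  arma::mat Xm(const_cast<double*>(x.begin()), N, cin, false, true);
  const int s3 = s * s * s;
  arma::mat Wm(cin, (long)s3 * cout);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int t = 0; t < s3; ++t)
        Wm(ci, t + (long)s3 * co) = w[t + (long)s3 * (ci + (long)cin * co)];
  arma::mat M = Xm * Wm; // N x (s3*cout)

  NumericVector y((long)Ho * Wo * Do * cout);
  double* yp = y.begin();
  const long planeO = (long)Ho * Wo;
  for (int co = 0; co < cout; ++co) {
    const double bco = (bias.size() == (R_xlen_t)cout) ? bias[co] : 0.0;
    double* yc = yp + (long)co * planeO * Do;
    if (bco != 0.0) std::fill(yc, yc + planeO * Do, bco);
    for (int c = 0; c < s; ++c)
      for (int b = 0; b < s; ++b)
        for (int a = 0; a < s; ++a) {
          const long t = a + s * (b + s * c);
          const double* m = M.colptr(t + (long)s3 * co);
          for (int d = 0; d < D; ++d)
            for (int ww = 0; ww < W; ++ww)
              for (int h = 0; h < H; ++h)
                yc[(s * h + a) + (long)Ho * (s * ww + b) + planeO * (s * d + c)]
                  += m[h + (long)H * (ww + (long)W * d)];
        }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Do, cout);
  return y;
}

// [[Rcpp::export(name = ".cpp_convT3d_backward")]]
List cpp_convT3d_backward(NumericVector x, IntegerVector xdim,
                          NumericVector w, NumericVector dy,
                          int s, int cin, int cout) {
  const int H = xdim[0], W = xdim[1], D = xdim[2];
  const int Ho = H * s, Wo = W * s, Do = D * s;
  const long N = (long)H * W * D;
  const int s3 = s * s * s;
  const long planeO = (long)Ho * Wo;

  // gather dy into dM (N x s3*cout)
  arma::mat dM(N, (long)s3 * cout);
  const double* dyp = dy.begin();
  arma::vec db(cout, arma::fill::zeros);
  for (int co = 0; co < cout; ++co) {
    const double* dyc = dyp + (long)co * planeO * Do;
    double acc = 0.0;
    for (long i = 0; i < planeO * Do; ++i) acc += dyc[i];
    db[co] = acc;
    for (int c = 0; c < s; ++c)
      for (int b = 0; b < s; ++b)
        for (int a = 0; a < s; ++a) {
          const long t = a + s * (b + s * c);
          double* m = dM.colptr(t + (long)s3 * co);
          for (int d = 0; d < D; ++d)
            for (int ww = 0; ww < W; ++ww)
              for (int h = 0; h < H; ++h)
                m[h + (long)H * (ww + (long)W * d)] =
                  dyc[(s * h + a) + (long)Ho * (s * ww + b) +
                      planeO * (s * d + c)];
        }
  }
  arma::mat Xm(const_cast<double*>(x.begin()), N, cin, false, true);
  arma::mat Wm(cin, (long)s3 * cout);
  const double* wp = w.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int t = 0; t < s3; ++t)
        Wm(ci, t + (long)s3 * co) = wp[t + (long)s3 * (ci + (long)cin * co)];

  arma::mat dXm = dM * Wm.t();          // N x cin
  arma::mat dWm = Xm.t() * dM;          // cin x (s3*cout)

  NumericVector dx(dXm.begin(), dXm.end());
  dx.attr("dim") = IntegerVector::create(H, W, D, cin);
  NumericVector dw((long)s3 * cin * cout);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int t = 0; t < s3; ++t)
        dw[t + (long)s3 * (ci + (long)cin * co)] = dWm(ci, t + (long)s3 * co);
  dw.attr("dim") = IntegerVector::create(s, s, s, cin, cout);
  NumericVector dbv(db.begin(), db.end());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = dbv);
}
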
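// Instance normalization on (H, W, D, C) volumes: per-channel spatial
// standardization plus affine. Single-pass C++ implementations; the R-level
// matrix reshaping this replaces dominated the training-step profile.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_instance_norm_forward")]]
List cpp_instance_norm_forward(NumericVector x, IntegerVector xdim,
                               NumericVector gamma, NumericVector beta,
                               double eps, bool relu = false) {
  const long N = (long)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector y(N * C);
  NumericVector xhat(N * C);
  NumericVector inv(C);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + N * c;
    // 4-way partial sums break the serial dependency chain so the loop
    // vectorizes without reassociation flags
    double s0 = 0, s1 = 0, s2a = 0, s3 = 0, q0 = 0, q1 = 0, q2 = 0, q3 = 0;
    long i = 0;
    for (; i + 4 <= N; i += 4) {
      s0 += xc[i];     q0 += xc[i] * xc[i];
      s1 += xc[i + 1]; q1 += xc[i + 1] * xc[i + 1];
      s2a += xc[i + 2]; q2 += xc[i + 2] * xc[i + 2];
      s3 += xc[i + 3]; q3 += xc[i + 3] * xc[i + 3];
    }
    for (; i < N; ++i) { s0 += xc[i]; q0 += xc[i] * xc[i]; }
    const double s = (s0 + s1) + (s2a + s3);
    const double s2 = (q0 + q1) + (q2 + q3);
    const double mu = s / N;
    const double var = std::max(0.0, s2 / N - mu * mu);
    const double iv = 1.0 / std::sqrt(var + eps);
    inv[c] = iv;
    const double g = gamma[c], b = beta[c];
    double* yc = yp + N * c;
    double* hc = hp + N * c;
    if (relu) {
      for (long i = 0; i < N; ++i) {
        const double h = (xc[i] - mu) * iv;
        hc[i] = h;
        const double v = g * h + b;
        yc[i] = v > 0 ? v : 0.0;
      }
    } else {
      for (long i = 0; i < N; ++i) {
        const double h = (xc[i] - mu) * iv;
        hc[i] = h;
        yc[i] = g * h + b;
      }
    }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// When `y` is supplied (fused IN+ReLU forward), the incoming gradient is
// first masked by y > 0.
// [[Rcpp::export(name = ".cpp_instance_norm_backward")]]
List cpp_instance_norm_backward(NumericVector dy, IntegerVector xdim,
                                NumericVector xhat, NumericVector inv,
                                NumericVector gamma,
                                Nullable<NumericVector> y = R_NilValue) {
  const long N = (long)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector dx(N * C), dgamma(C), dbeta(C);
  const double* dyp = dy.begin();
  const double* hp = xhat.begin();
  const double* ymask = y.isNotNull() ? NumericVector(y).begin() : nullptr;
  double* dxp = dx.begin();
  std::vector<double> dybuf;
  if (ymask) dybuf.resize(N);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dyp + N * c;
    if (ymask) {
      const double* yc = ymask + N * c;
      for (long i = 0; i < N; ++i) dybuf[i] = yc[i] > 0 ? dyc[i] : 0.0;
      dyc = dybuf.data();
    }
    const double* hc = hp + N * c;
    double g0 = 0, g1 = 0, g2 = 0, g3 = 0, b0 = 0, b1 = 0, b2 = 0, b3 = 0;
    long i = 0;
    for (; i + 4 <= N; i += 4) {
      g0 += dyc[i] * hc[i];         b0 += dyc[i];
      g1 += dyc[i + 1] * hc[i + 1]; b1 += dyc[i + 1];
      g2 += dyc[i + 2] * hc[i + 2]; b2 += dyc[i + 2];
      g3 += dyc[i + 3] * hc[i + 3]; b3 += dyc[i + 3];
    }
    for (; i < N; ++i) { g0 += dyc[i] * hc[i]; b0 += dyc[i]; }
    const double sg = (g0 + g1) + (g2 + g3);
    const double sb = (b0 + b1) + (b2 + b3);
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gamma[c];
    const double m1 = g * sb / N;          // mean of dxhat
    const double m2 = g * sg / N;          // mean of dxhat * xhat
    const double iv = inv[c];
    double* dxc = dxp + N * c;
    for (long i = 0; i < N; ++i)
      dxc[i] = (g * dyc[i] - m1 - hc[i] * m2) * iv;
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ReLU forward/backward without allocating an R-level logical mask.
// [[Rcpp::export(name = ".cpp_relu_forward")]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin(); double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_backward")]]
NumericVector cpp_relu_backward(NumericVector g, NumericVector y) {
  NumericVector dx(g.size());
  const double* gp = g.begin(); const double* yp = y.begin();
  double* dp = dx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) dp[i] = yp[i] > 0 ? gp[i] : 0.0;
  dx.attr("dim") = g.attr("dim");
  return dx;
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Training allocates/frees hundreds of MB of activation arrays per step;
// keeping big blocks on the heap free list (instead of mmap/munmap churn
// with kernel re-zeroing) removes most of the system-time overhead.
// [[Rcpp::export(name = ".cpp_tune_allocator")]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}
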
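// Trilinear resizing, 2x average pooling, and continuous-location sampling
// (with gradients w.r.t. both features and coordinates, as needed by the
// deformable attention module). Layout (H, W, D, C), column-major.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {
inline double clampd(double v, double lo, double hi) {
  if (!std::isfinite(v)) return lo;   // non-finite coords clamp to the border
  return v < lo ? lo : (v > hi ? hi : v);
}
// half-pixel-centre source coordinate for output index i (align_corners=FALSE)
inline double src_coord(int i, double scale) {
  return (i + 0.5) * scale - 0.5;
}
}

// [[Rcpp::export(name = ".cpp_trilinear_resize")]]
NumericVector cpp_trilinear_resize(NumericVector x, IntegerVector xdim,
                                   IntegerVector odim) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3];
  const int Ho = odim[0], Wo = odim[1], Do = odim[2];
  const double sh = (double)H / Ho, sw = (double)W / Wo, sd = (double)D / Do;
  NumericVector y((long)Ho * Wo * Do * C);
  const long planeI = (long)H * W, volI = planeI * D;
  const long planeO = (long)Ho * Wo, volO = planeO * Do;

  std::vector<int> h0(Ho), w0(Wo), d0(Do);
  std::vector<double> fh(Ho), fw(Wo), fd(Do);
  for (int i = 0; i < Ho; ++i) {
    double s = clampd(src_coord(i, sh), 0.0, H - 1.0);
    h0[i] = std::min((int)s, H - 2 < 0 ? 0 : H - 2); fh[i] = s - h0[i];
    if (H == 1) { h0[i] = 0; fh[i] = 0.0; }
  }
  for (int i = 0; i < Wo; ++i) {
    double s = clampd(src_coord(i, sw), 0.0, W - 1.0);
    w0[i] = std::min((int)s, W - 2 < 0 ? 0 : W - 2); fw[i] = s - w0[i];
    if (W == 1) { w0[i] = 0; fw[i] = 0.0; }
  }
  for (int i = 0; i < Do; ++i) {
    double s = clampd(src_coord(i, sd), 0.0, D - 1.0);
    d0[i] = std::min((int)s, D - 2 < 0 ? 0 : D - 2); fd[i] = s - d0[i];
    if (D == 1) { d0[i] = 0; fd[i] = 0.0; }
  }
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (long)c * volI;
    double* yc = yp + (long)c * volO;
    for (int d = 0; d < Do; ++d) {
      const int dd = d0[d]; const double gd = fd[d];
      const int d1 = (D > 1) ? dd + 1 : dd;
      for (int w = 0; w < Wo; ++w) {
        const int ww = w0[w]; const double gw = fw[w];
        const int w1 = (W > 1) ? ww + 1 : ww;
        for (int h = 0; h < Ho; ++h) {
          const int hh = h0[h]; const double gh = fh[h];
          const int h1 = (H > 1) ? hh + 1 : hh;
          const double v000 = xc[hh + H * (long)ww + planeI * dd];
          const double v100 = xc[h1 + H * (long)ww + planeI * dd];
          const double v010 = xc[hh + H * (long)w1 + planeI * dd];
          const double v110 = xc[h1 + H * (long)w1 + planeI * dd];
          const double v001 = xc[hh + H * (long)ww + planeI * d1];
          const double v101 = xc[h1 + H * (long)ww + planeI * d1];
          const double v011 = xc[hh + H * (long)w1 + planeI * d1];
          const double v111 = xc[h1 + H * (long)w1 + planeI * d1];
          const double c00 = v000 * (1 - gh) + v100 * gh;
          const double c10 = v010 * (1 - gh) + v110 * gh;
          const double c01 = v001 * (1 - gh) + v101 * gh;
          const double c11 = v011 * (1 - gh) + v111 * gh;
          const double c0 = c00 * (1 - gw) + c10 * gw;
          const double c1 = c01 * (1 - gw) + c11 * gw;
          yc[h + (long)Ho * w + planeO * d] = c0 * (1 - gd) + c1 * gd;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Do, C);
  return y;
}

// adjoint of cpp_trilinear_resize
// [[Rcpp::export(name = ".cpp_trilinear_resize_backward")]]
NumericVector cpp_trilinear_resize_backward(NumericVector dy,
                                            IntegerVector xdim,
                                            IntegerVector odim) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3];
  const int Ho = odim[0], Wo = odim[1], Do = odim[2];
  const double sh = (double)H / Ho, sw = (double)W / Wo, sd = (double)D / Do;
  NumericVector dx((long)H * W * D * C);
  const long planeI = (long)H * W, volI = planeI * D;
  const long planeO = (long)Ho * Wo, volO = planeO * Do;

  std::vector<int> h0(Ho), w0(Wo), d0(Do);
  std::vector<double> fh(Ho), fw(Wo), fd(Do);
  for (int i = 0; i < Ho; ++i) {
    double s = clampd(src_coord(i, sh), 0.0, H - 1.0);
    h0[i] = std::min((int)s, H - 2 < 0 ? 0 : H - 2); fh[i] = s - h0[i];
    if (H == 1) { h0[i] = 0; fh[i] = 0.0; }
  }
  for (int i = 0; i < Wo; ++i) {
    double s = clampd(src_coord(i, sw), 0.0, W - 1.0);
    w0[i] = std::min((int)s, W - 2 < 0 ? 0 : W - 2); fw[i] = s - w0[i];
    if (W == 1) { w0[i] = 0; fw[i] = 0.0; }
  }
  for (int i = 0; i < Do; ++i) {
    double s = clampd(src_coord(i, sd), 0.0, D - 1.0);
    d0[i] = std::min((int)s, D - 2 < 0 ? 0 : D - 2); fd[i] = s - d0[i];
    if (D == 1) { d0[i] = 0; fd[i] = 0.0; }
  }
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = dxp + (long)c * volI;
    const double* yc = dyp + (long)c * volO;
    for (int d = 0; d < Do; ++d) {
      const int dd = d0[d]; const double gd = fd[d];
      const int d1 = (D > 1) ? dd + 1 : dd;
      for (int w = 0; w < Wo; ++w) {
        const int ww = w0[w]; const double gw = fw[w];
        const int w1 = (W > 1) ? ww + 1 : ww;
        for (int h = 0; h < Ho; ++h) {
          const int hh = h0[h]; const double gh = fh[h];
          const int h1 = (H > 1) ? hh + 1 : hh;
          const double g = yc[h + (long)Ho * w + planeO * d];
          xc[hh + H * (long)ww + planeI * dd] += g * (1 - gh) * (1 - gw) * (1 - gd);
          xc[h1 + H * (long)ww + planeI * dd] += g * gh * (1 - gw) * (1 - gd);
          xc[hh + H * (long)w1 + planeI * dd] += g * (1 - gh) * gw * (1 - gd);
          xc[h1 + H * (long)w1 + planeI * dd] += g * gh * gw * (1 - gd);
          xc[hh + H * (long)ww + planeI * d1] += g * (1 - gh) * (1 - gw) * gd;
          xc[h1 + H * (long)ww + planeI * d1] += g * gh * (1 - gw) * gd;
          xc[hh + H * (long)w1 + planeI * d1] += g * (1 - gh) * gw * gd;
          xc[h1 + H * (long)w1 + planeI * d1] += g * gh * gw * gd;
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, D, C);
  return dx;
}

// [[Rcpp::export(name = ".cpp_avgpool2_forward")]]
NumericVector cpp_avgpool2_forward(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3];
  const int Ho = H / 2, Wo = W / 2, Do = D / 2;
  NumericVector y((long)Ho * Wo * Do * C);
  const long planeI = (long)H * W, volI = planeI * D;
  const long planeO = (long)Ho * Wo, volO = planeO * Do;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c)
    for (int d = 0; d < Do; ++d)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double acc = 0.0;
          for (int cc = 0; cc < 2; ++cc)
            for (int bb = 0; bb < 2; ++bb)
              for (int aa = 0; aa < 2; ++aa)
                acc += xp[(2 * h + aa) + (long)H * (2 * w + bb) +
                          planeI * (2 * d + cc) + volI * c];
          yp[h + (long)Ho * w + planeO * d + volO * c] = acc / 8.0;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Do, C);
  return y;
}

// [[Rcpp::export(name = ".cpp_avgpool2_backward")]]
NumericVector cpp_avgpool2_backward(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3];
  const int Ho = H / 2, Wo = W / 2, Do = D / 2;
  NumericVector dx((long)H * W * D * C);
  const long planeI = (long)H * W, volI = planeI * D;
  const long planeO = (long)Ho * Wo, volO = planeO * Do;
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int d = 0; d < Do; ++d)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const double g = dyp[h + (long)Ho * w + planeO * d + volO * c] / 8.0;
          for (int cc = 0; cc < 2; ++cc)
            for (int bb = 0; bb < 2; ++bb)
              for (int aa = 0; aa < 2; ++aa)
                dxp[(2 * h + aa) + (long)H * (2 * w + bb) +
                    planeI * (2 * d + cc) + volI * c] += g;
        }
  dx.attr("dim") = IntegerVector::create(H, W, D, C);
  return dx;
}

// Sample a multichannel grid at continuous voxel coordinates (0-based),
// trilinear, clamped to the border. coords: N x 3 (h, w, d).
// Returns N x C.
// [[Rcpp::export(name = ".cpp_grid_sample")]]
NumericMatrix cpp_grid_sample(NumericVector x, IntegerVector xdim,
                              NumericMatrix coords) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3];
  const int N = coords.nrow();
  const long planeI = (long)H * W, volI = planeI * D;
  NumericMatrix out(N, C);
  const double* xp = x.begin();
  for (int i = 0; i < N; ++i) {
    double h = clampd(coords(i, 0), 0.0, H - 1.0);
    double w = clampd(coords(i, 1), 0.0, W - 1.0);
    double d = clampd(coords(i, 2), 0.0, D - 1.0);
    int hh = std::min((int)h, std::max(H - 2, 0));
    int ww = std::min((int)w, std::max(W - 2, 0));
    int dd = std::min((int)d, std::max(D - 2, 0));
    const double gh = (H > 1) ? h - hh : 0.0;
    const double gw = (W > 1) ? w - ww : 0.0;
    const double gd = (D > 1) ? d - dd : 0.0;
    const int h1 = (H > 1) ? hh + 1 : hh;
    const int w1 = (W > 1) ? ww + 1 : ww;
    const int d1 = (D > 1) ? dd + 1 : dd;
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (long)c * volI;
      const double v000 = xc[hh + (long)H * ww + planeI * dd];
      const double v100 = xc[h1 + (long)H * ww + planeI * dd];
      const double v010 = xc[hh + (long)H * w1 + planeI * dd];
      const double v110 = xc[h1 + (long)H * w1 + planeI * dd];
      const double v001 = xc[hh + (long)H * ww + planeI * d1];
      const double v101 = xc[h1 + (long)H * ww + planeI * d1];
      const double v011 = xc[hh + (long)H * w1 + planeI * d1];
      const double v111 = xc[h1 + (long)H * w1 + planeI * d1];
      const double c00 = v000 * (1 - gh) + v100 * gh;
      const double c10 = v010 * (1 - gh) + v110 * gh;
      const double c01 = v001 * (1 - gh) + v101 * gh;
      const double c11 = v011 * (1 - gh) + v111 * gh;
      out(i, c) = (c00 * (1 - gw) + c10 * gw) * (1 - gd) +
                  (c01 * (1 - gw) + c11 * gw) * gd;
    }
  }
  return out;
}

// Backward of cpp_grid_sample: gradients w.r.t. the grid and the coordinates.
// Coordinate gradients are zero where the coordinate was clamped (subgradient).
// [[Rcpp::export(name = ".cpp_grid_sample_backward")]]
List cpp_grid_sample_backward(NumericVector x, IntegerVector xdim,
                              NumericMatrix coords, NumericMatrix dout) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3];
  const int N = coords.nrow();
  const long planeI = (long)H * W, volI = planeI * D;
  NumericVector dx((long)H * W * D * C);
  NumericMatrix dcoords(N, 3);
  const double* xp = x.begin();
  double* dxp = dx.begin();
  for (int i = 0; i < N; ++i) {
    const double rh = coords(i, 0), rw = coords(i, 1), rd = coords(i, 2);
    double h = clampd(rh, 0.0, H - 1.0);
    double w = clampd(rw, 0.0, W - 1.0);
    double d = clampd(rd, 0.0, D - 1.0);
    const bool inh = (rh > 0.0 && rh < H - 1.0 && H > 1);
    const bool inw = (rw > 0.0 && rw < W - 1.0 && W > 1);
    const bool ind = (rd > 0.0 && rd < D - 1.0 && D > 1);
    int hh = std::min((int)h, std::max(H - 2, 0));
    int ww = std::min((int)w, std::max(W - 2, 0));
    int dd = std::min((int)d, std::max(D - 2, 0));
    const double gh = (H > 1) ? h - hh : 0.0;
    const double gw = (W > 1) ? w - ww : 0.0;
    const double gd = (D > 1) ? d - dd : 0.0;
    const int h1 = (H > 1) ? hh + 1 : hh;
    const int w1 = (W > 1) ? ww + 1 : ww;
    const int d1 = (D > 1) ? dd + 1 : dd;
    double acc_h = 0.0, acc_w = 0.0, acc_d = 0.0;
    for (int c = 0; c < C; ++c) {
      const double g = dout(i, c);
      if (g == 0.0) continue;
      const double* xc = xp + (long)c * volI;
      double* dxc = dxp + (long)c * volI;
      const double v000 = xc[hh + (long)H * ww + planeI * dd];
      const double v100 = xc[h1 + (long)H * ww + planeI * dd];
      const double v010 = xc[hh + (long)H * w1 + planeI * dd];
      const double v110 = xc[h1 + (long)H * w1 + planeI * dd];
      const double v001 = xc[hh + (long)H * ww + planeI * d1];
      const double v101 = xc[h1 + (long)H * ww + planeI * d1];
      const double v011 = xc[hh + (long)H * w1 + planeI * d1];
      const double v111 = xc[h1 + (long)H * w1 + planeI * d1];
      // grid gradients
      dxc[hh + (long)H * ww + planeI * dd] += g * (1 - gh) * (1 - gw) * (1 - gd);
      dxc[h1 + (long)H * ww + planeI * dd] += g * gh * (1 - gw) * (1 - gd);
      dxc[hh + (long)H * w1 + planeI * dd] += g * (1 - gh) * gw * (1 - gd);
      dxc[h1 + (long)H * w1 + planeI * dd] += g * gh * gw * (1 - gd);
      dxc[hh + (long)H * ww + planeI * d1] += g * (1 - gh) * (1 - gw) * gd;
      dxc[h1 + (long)H * ww + planeI * d1] += g * gh * (1 - gw) * gd;
      dxc[hh + (long)H * w1 + planeI * d1] += g * (1 - gh) * gw * gd;
      dxc[h1 + (long)H * w1 + planeI * d1] += g * gh * gw * gd;
      // coordinate gradients
      const double dh = (v100 - v000) * (1 - gw) * (1 - gd) +
                        (v110 - v010) * gw * (1 - gd) +
                        (v101 - v001) * (1 - gw) * gd +
                        (v111 - v011) * gw * gd;
      const double dw_ = (v010 - v000) * (1 - gh) * (1 - gd) +
                         (v110 - v100) * gh * (1 - gd) +
                         (v011 - v001) * (1 - gh) * gd +
                         (v111 - v101) * gh * gd;
      const double dd_ = (v001 - v000) * (1 - gh) * (1 - gw) +
                         (v101 - v100) * gh * (1 - gw) +
                         (v011 - v010) * (1 - gh) * gw +
                         (v111 - v110) * gh * gw;
      acc_h += g * dh; acc_w += g * dw_; acc_d += g * dd_;
    }
    dcoords(i, 0) = inh ? acc_h : 0.0;
    dcoords(i, 1) = inw ? acc_w : 0.0;
    dcoords(i, 2) = ind ? acc_d : 0.0;
  }
  dx.attr("dim") = IntegerVector::create(H, W, D, C);
  return List::create(_["dx"] = dx, _["dcoords"] = dcoords);
}

// Nearest-neighbour sampling of a single-channel grid at continuous
// coordinates; used for mask resampling in the augmentation pipeline.
// Out-of-range coordinates return `fill`.
// [[Rcpp::export(name = ".cpp_sample_points")]]
NumericVector cpp_sample_points(NumericVector x, IntegerVector xdim,
                                NumericMatrix coords, std::string method,
                                double fill) {
  const int H = xdim[0], W = xdim[1], D = xdim[2];
  const int N = coords.nrow();
  const long planeI = (long)H * W;
  NumericVector out(N);
  const double* xp = x.begin();
  const bool nearest = (method == "nearest");
  for (int i = 0; i < N; ++i) {
    const double h = coords(i, 0), w = coords(i, 1), d = coords(i, 2);
    if (h < -0.5 || h > H - 0.5 || w < -0.5 || w > W - 0.5 ||
        d < -0.5 || d > D - 0.5) { out[i] = fill; continue; }
    if (nearest) {
      int hh = (int)std::lround(clampd(h, 0.0, H - 1.0));
      int ww = (int)std::lround(clampd(w, 0.0, W - 1.0));
      int dd = (int)std::lround(clampd(d, 0.0, D - 1.0));
      out[i] = xp[hh + (long)H * ww + planeI * dd];
    } else {
      double hc = clampd(h, 0.0, H - 1.0);
      double wc = clampd(w, 0.0, W - 1.0);
      double dc = clampd(d, 0.0, D - 1.0);
      int hh = std::min((int)hc, std::max(H - 2, 0));
      int ww = std::min((int)wc, std::max(W - 2, 0));
      int dd = std::min((int)dc, std::max(D - 2, 0));
      const double gh = (H > 1) ? hc - hh : 0.0;
      const double gw = (W > 1) ? wc - ww : 0.0;
      const double gd = (D > 1) ? dc - dd : 0.0;
      const int h1 = (H > 1) ? hh + 1 : hh;
      const int w1 = (W > 1) ? ww + 1 : ww;
      const int d1 = (D > 1) ? dd + 1 : dd;
      const double v000 = xp[hh + (long)H * ww + planeI * dd];
      const double v100 = xp[h1 + (long)H * ww + planeI * dd];
      const double v010 = xp[hh + (long)H * w1 + planeI * dd];
      const double v110 = xp[h1 + (long)H * w1 + planeI * dd];
      const double v001 = xp[hh + (long)H * ww + planeI * d1];
      const double v101 = xp[h1 + (long)H * ww + planeI * d1];
      const double v011 = xp[hh + (long)H * w1 + planeI * d1];
      const double v111 = xp[h1 + (long)H * w1 + planeI * d1];
      const double c00 = v000 * (1 - gh) + v100 * gh;
      const double c10 = v010 * (1 - gh) + v110 * gh;
      const double c01 = v001 * (1 - gh) + v101 * gh;
      const double c11 = v011 * (1 - gh) + v111 * gh;
      out[i] = (c00 * (1 - gw) + c10 * gw) * (1 - gd) +
               (c01 * (1 - gw) + c11 * gw) * gd;
    }
  }
  return out;
}
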
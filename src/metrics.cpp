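// Exact anisotropic Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope-of-parabolas algorithm, run separably per axis with the
// physical voxel size as the cell width) plus 6-connected component labelling.
// Used by the Hausdorff metric: directed distances from every foreground
// voxel of one mask to the nearest foreground voxel of the other are read off
// the other mask's distance map, which is exact for voxel-centre point sets.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();
// Large finite sentinel for "no source yet": keeps the parabola-intersection
// arithmetic finite (INF - INF would poison it with NaN on mixed lines).
const double BIG = 1e15;

// 1D squared distance transform over samples with physical cell size `step`.
// f: input squared distances; out: result; n: length.
void dt1d(const double* f, double* out, int n, double step,
          std::vector<int>& v, std::vector<double>& z) {
  v.resize(n); z.resize(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qs = q * step;
    double s;
    while (true) {
      double ps = v[k] * step;
      s = ((f[q] + qs * qs) - (f[v[k]] + ps * ps)) / (2 * qs - 2 * ps);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * step;
    while (z[k + 1] < qs) ++k;
    double d = qs - v[k] * step;
    out[q] = d * d + f[v[k]];
  }
}

} // namespace

// Squared Euclidean distance (physical units) from every voxel to the nearest
// foreground voxel of `mask` (values 0/1). Returns Inf everywhere if the mask
// is empty.
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int H = dim[0], W = dim[1], D = dim[2];
  const long planeHW = (long)H * W;
  NumericVector g((long)H * W * D);
  for (long i = 0; i < (long)H * W * D; ++i)
    g[i] = mask[i] ? 0.0 : BIG;

  std::vector<int> v; std::vector<double> z;
  std::vector<double> buf(std::max(H, std::max(W, D)));
  std::vector<double> fb(std::max(H, std::max(W, D)));

  // axis H (contiguous)
  for (int d = 0; d < D; ++d)
    for (int w = 0; w < W; ++w) {
      double* col = g.begin() + (long)H * w + planeHW * d;
      bool any = false;
      for (int h = 0; h < H; ++h) { fb[h] = col[h]; if (col[h] < BIG) any = true; }
      if (!any) continue;
      dt1d(fb.data(), buf.data(), H, spacing[0], v, z);
      for (int h = 0; h < H; ++h) col[h] = buf[h];
    }
  // axis W
  for (int d = 0; d < D; ++d)
    for (int h = 0; h < H; ++h) {
      double* base = g.begin() + h + planeHW * d;
      bool any = false;
      for (int w = 0; w < W; ++w) { fb[w] = base[(long)H * w]; if (fb[w] < BIG) any = true; }
      if (!any) continue;
      dt1d(fb.data(), buf.data(), W, spacing[1], v, z);
      for (int w = 0; w < W; ++w) base[(long)H * w] = buf[w];
    }
  // axis D
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double* base = g.begin() + h + (long)H * w;
      bool any = false;
      for (int d = 0; d < D; ++d) { fb[d] = base[planeHW * d]; if (fb[d] < BIG) any = true; }
      if (!any) continue;
      dt1d(fb.data(), buf.data(), D, spacing[2], v, z);
      for (int d = 0; d < D; ++d) base[planeHW * d] = buf[d];
    }
  g.attr("dim") = IntegerVector::create(H, W, D);
  return g;
}

// 6-connected component labelling of a binary mask. Labels 1..n in first-seen
// (raster) order; background 0.
// [[Rcpp::export(name = ".cpp_label6")]]
IntegerVector cpp_label6(IntegerVector mask, IntegerVector dim) {
  const int H = dim[0], W = dim[1], D = dim[2];
  const long planeHW = (long)H * W, n = planeHW * D;
  IntegerVector lab(n);
  std::vector<long> stack;
  int next = 0;
  for (long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      long cur = stack.back(); stack.pop_back();
      int d = (int)(cur / planeHW);
      long rem = cur % planeHW;
      int w = (int)(rem / H);
      int h = (int)(rem % H);
      const int dh[6] = {-1, 1, 0, 0, 0, 0};
      const int dw[6] = {0, 0, -1, 1, 0, 0};
      const int dd[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int nh = h + dh[t], nw = w + dw[t], nd = d + dd[t];
        if (nh < 0 || nh >= H || nw < 0 || nw >= W || nd < 0 || nd >= D)
          continue;
        long ni = nh + (long)H * nw + planeHW * nd;
        if (mask[ni] && !lab[ni]) { lab[ni] = next; stack.push_back(ni); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(H, W, D);
  return lab;
}
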
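// Separable valid-mode filtering (local SSIM statistics) and overlap-aware
// patch merging with extended-precision accumulation.

#include <Rcpp.h>
using namespace Rcpp;

// Correlate along one axis in valid mode with kernel w.
static NumericVector filt_axis(const NumericVector& x, int axis, const NumericVector& w) {
  IntegerVector d = x.attr("dim");
  int L = w.size();
  IntegerVector od = clone(d);
  od[axis] = d[axis] - L + 1;
  if (od[axis] < 1) stop("volume smaller than filter window along axis %d", axis + 1);
  NumericVector y((R_xlen_t)od[0] * od[1] * od[2]);
  y.attr("dim") = od;
  R_xlen_t st = 1;
  for (int a = 0; a < axis; ++a) st *= d[a];
  // iterate output positions directly
  for (int k = 0; k < od[2]; ++k)
    for (int j = 0; j < od[1]; ++j)
      for (int i = 0; i < od[0]; ++i) {
        int ii = i, jj = j, kk = k;  // input start index along axis = output index
        R_xlen_t base = ii + (R_xlen_t)d[0] * (jj + (R_xlen_t)d[1] * kk);
        double s = 0;
        const double* p = x.begin() + base;
        for (int t = 0; t < L; ++t) s += w[t] * p[(R_xlen_t)t * st];
        y[i + (R_xlen_t)od[0] * (j + (R_xlen_t)od[1] * k)] = s;
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_sepfilter3_valid(NumericVector x, NumericVector w) {
  NumericVector y = filt_axis(x, 0, w);
  y = filt_axis(y, 1, w);
  y = filt_axis(y, 2, w);
  return y;
}

// Sum per-patch predictions into a base map and divide by per-voxel overlap
// counts. Accumulation in long double so that patches cut from a single
// volume merge back to it bit-for-bit.
// [[Rcpp::export]]
NumericVector cpp_merge_patches(List preds, IntegerMatrix offs, IntegerVector grid) {
  int gx = grid[0], gy = grid[1], gz = grid[2];
  R_xlen_t n = (R_xlen_t)gx * gy * gz;
  std::vector<long double> acc(n, 0.0L);
  std::vector<int> cnt(n, 0);
  for (int p = 0; p < preds.size(); ++p) {
    NumericVector pr = preds[p];
    IntegerVector pd = pr.attr("dim");
    int px = pd[0], py = pd[1], pz = pd[2];
    int o1 = offs(p, 0), o2 = offs(p, 1), o3 = offs(p, 2);
    R_xlen_t q = 0;
    for (int k = 0; k < pz; ++k)
      for (int j = 0; j < py; ++j) {
        R_xlen_t base = (o1) + (R_xlen_t)gx * ((o2 + j) + (R_xlen_t)gy * (o3 + k));
        for (int i = 0; i < px; ++i, ++q) {
          acc[base + i] += (long double)pr[q];
          cnt[base + i] += 1;
        }
      }
  }
  NumericVector out(n);
  out.attr("dim") = grid;
  for (R_xlen_t v = 0; v < n; ++v) {
    if (cnt[v] == 0) stop("patch layout leaves voxels uncovered");
    out[v] = (double)(acc[v] / (long double)cnt[v]);
  }
  return out;
}
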
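// Resampling kernels: separable cubic (Catmull-Rom) interpolation along one
// axis for grid-to-grid resampling, and trilinear sampling under an affine
// index map for volume rotation.

#include <Rcpp.h>
using namespace Rcpp;

// Sample s[i] with linear extrapolation beyond the ends, so that linear
// intensity ramps are reproduced exactly through the boundary fringe.
static inline double ghost(const double* s, int n, int st, int i) {
  if (n == 1) return s[0];
  if (i < 0) return s[0] + (double)i * (s[st] - s[0]);
  if (i >= n) return s[(R_xlen_t)(n - 1) * st] +
                     (double)(i - n + 1) *
                     (s[(R_xlen_t)(n - 1) * st] - s[(R_xlen_t)(n - 2) * st]);
  return s[(R_xlen_t)i * st];
}

// Catmull-Rom cubic at continuous index t along a strided line.
static inline double cubic1(const double* s, int n, int st, double t) {
  int i1 = (int)std::floor(t);
  double f = t - i1;
  double s0 = ghost(s, n, st, i1 - 1), s1 = ghost(s, n, st, i1),
         s2 = ghost(s, n, st, i1 + 1), s3 = ghost(s, n, st, i1 + 2);
  return 0.5 * (2.0 * s1 + f * (-s0 + s2) +
                f * f * (2.0 * s0 - 5.0 * s1 + 4.0 * s2 - s3) +
                f * f * f * (-s0 + 3.0 * s1 - 3.0 * s2 + s3));
}

// Resample a 3D array along `axis` (0-based) at continuous 0-based index
// positions `coords`; other axes untouched.
// [[Rcpp::export]]
NumericVector cpp_resample_axis(NumericVector x, int axis, NumericVector coords) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int n = d[axis], m = coords.size();
  IntegerVector od = clone(d);
  od[axis] = m;
  NumericVector y((R_xlen_t)od[0] * od[1] * od[2]);
  y.attr("dim") = od;

  // stride along the axis and iteration over the perpendicular plane
  R_xlen_t st = 1;
  for (int a = 0; a < axis; ++a) st *= d[a];
  int p1 = (axis == 0) ? ny : nx;              // first perpendicular dim
  int p2 = (axis == 2) ? ny : nz;              // second perpendicular dim
  R_xlen_t st1, st2, ost1, ost2, ost = st;
  if (axis == 0)      { st1 = nx;      st2 = (R_xlen_t)nx * ny; }
  else if (axis == 1) { st1 = 1;       st2 = (R_xlen_t)nx * ny; }
  else                { st1 = 1;       st2 = nx; }
  if (axis == 0)      { ost1 = m;      ost2 = (R_xlen_t)m * ny; }
  else if (axis == 1) { ost1 = 1;      ost2 = (R_xlen_t)nx * m; }
  else                { ost1 = 1;      ost2 = nx; }

  for (int b = 0; b < p2; ++b)
    for (int a = 0; a < p1; ++a) {
      const double* src = x.begin() + a * st1 + b * st2;
      double* dst = y.begin() + a * ost1 + b * ost2;
      for (int i = 0; i < m; ++i) dst[(R_xlen_t)i * ost] = cubic1(src, n, (int)st, coords[i]);
    }
  return y;
}

// Trilinear sampling of x at positions A %*% c(i,j,k,1) (0-based index
// coordinates); positions outside the sample hull get `fill`.
// [[Rcpp::export]]
NumericVector cpp_affine_trilinear(NumericVector x, NumericMatrix A,
                                   IntegerVector outdim, double fill) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector y((R_xlen_t)ox * oy * oz, fill);
  y.attr("dim") = outdim;
  const double* X = x.begin();
  R_xlen_t o = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++o) {
        double sx = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + A(0, 3);
        double sy = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + A(1, 3);
        double sz = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + A(2, 3);
        if (sx < 0 || sx > nx - 1 || sy < 0 || sy > ny - 1 || sz < 0 || sz > nz - 1)
          continue;
        int i0 = (int)std::floor(sx); if (i0 > nx - 2) i0 = nx - 2; if (nx == 1) i0 = 0;
        int j0 = (int)std::floor(sy); if (j0 > ny - 2) j0 = ny - 2; if (ny == 1) j0 = 0;
        int k0 = (int)std::floor(sz); if (k0 > nz - 2) k0 = nz - 2; if (nz == 1) k0 = 0;
        double fx = sx - i0, fy = sy - j0, fz = sz - k0;
        int i1 = (nx == 1) ? i0 : i0 + 1, j1 = (ny == 1) ? j0 : j0 + 1,
            k1 = (nz == 1) ? k0 : k0 + 1;
        #define AT(a, b, c) X[(a) + (R_xlen_t)nx * ((b) + (R_xlen_t)ny * (c))]
        double v =
          (1 - fx) * (1 - fy) * (1 - fz) * AT(i0, j0, k0) +
          fx * (1 - fy) * (1 - fz) * AT(i1, j0, k0) +
          (1 - fx) * fy * (1 - fz) * AT(i0, j1, k0) +
          fx * fy * (1 - fz) * AT(i1, j1, k0) +
          (1 - fx) * (1 - fy) * fz * AT(i0, j0, k1) +
          fx * (1 - fy) * fz * AT(i1, j0, k1) +
          (1 - fx) * fy * fz * AT(i0, j1, k1) +
          fx * fy * fz * AT(i1, j1, k1);
        #undef AT
        y[o] = v;
      }
  return y;
}
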
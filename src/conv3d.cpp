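// 3D convolution primitives for the U-Net / PatchGAN stacks.
// Arrays are R column-major with dims (nx, ny, nz, channels).
// Convolutions are expressed as im2col + BLAS matrix products; the
// transpose convolution reuses the same column <-> array scatter/gather
// with the roles of the voxel grids swapped.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t id4(int i, int j, int k, int c, const int* d) {
  return i + (R_xlen_t)d[0] * (j + (R_xlen_t)d[1] * (k + (R_xlen_t)d[2] * c));
}

// Gather columns from `arr` (dims adim, nc channels). Column o indexes the
// grid (gx, gy, gz); row r = kx + K*(ky + K*(kz + K*c)). Array position for
// (grid point g, kernel offset kk) is g*S - P + kk per axis; out-of-bounds
// entries stay zero.
static arma::mat im2col3(const double* arr, const int* adim, int nc,
                         int K, int S, int P, int gx, int gy, int gz) {
  arma::mat cols((arma::uword)K * K * K * nc, (arma::uword)gx * gy * gz,
                 arma::fill::zeros);
  for (int c = 0; c < nc; ++c)
    for (int kz = 0; kz < K; ++kz)
      for (int ky = 0; ky < K; ++ky)
        for (int kx = 0; kx < K; ++kx) {
          arma::uword r = kx + (arma::uword)K * (ky + (arma::uword)K * (kz + (arma::uword)K * c));
          for (int k = 0; k < gz; ++k) {
            int iz = k * S - P + kz;
            if (iz < 0 || iz >= adim[2]) continue;
            for (int j = 0; j < gy; ++j) {
              int iy = j * S - P + ky;
              if (iy < 0 || iy >= adim[1]) continue;
              const double* src = arr + id4(0, iy, iz, c, adim);
              R_xlen_t ob = (R_xlen_t)gx * (j + (R_xlen_t)gy * k);
              for (int i = 0; i < gx; ++i) {
                int ix = i * S - P + kx;
                if (ix < 0 || ix >= adim[0]) continue;
                cols(r, ob + i) = src[ix];
              }
            }
          }
        }
  return cols;
}

// Adjoint of im2col3: scatter-add columns back into `arr`.
static void col2im3(double* arr, const int* adim, int nc, const arma::mat& cols,
                    int K, int S, int P, int gx, int gy, int gz) {
  for (int c = 0; c < nc; ++c)
    for (int kz = 0; kz < K; ++kz)
      for (int ky = 0; ky < K; ++ky)
        for (int kx = 0; kx < K; ++kx) {
          arma::uword r = kx + (arma::uword)K * (ky + (arma::uword)K * (kz + (arma::uword)K * c));
          for (int k = 0; k < gz; ++k) {
            int iz = k * S - P + kz;
            if (iz < 0 || iz >= adim[2]) continue;
            for (int j = 0; j < gy; ++j) {
              int iy = j * S - P + ky;
              if (iy < 0 || iy >= adim[1]) continue;
              double* dst = arr + id4(0, iy, iz, c, adim);
              R_xlen_t ob = (R_xlen_t)gx * (j + (R_xlen_t)gy * k);
              for (int i = 0; i < gx; ++i) {
                int ix = i * S - P + kx;
                if (ix < 0 || ix >= adim[0]) continue;
                dst[ix] += cols(r, ob + i);
              }
            }
          }
        }
}

static NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericMatrix W, NumericVector b,
                             int K, int S, int P) {
  IntegerVector xd = x.attr("dim");
  int ic = xd[3];
  int ox = (xd[0] + 2 * P - K) / S + 1;
  int oy = (xd[1] + 2 * P - K) / S + 1;
  int oz = (xd[2] + 2 * P - K) / S + 1;
  int oc = W.ncol();
  arma::mat cols = im2col3(x.begin(), xd.begin(), ic, K, S, P, ox, oy, oz);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat Y = Wm.t() * cols;                       // oc x nOut
  arma::vec bv(b.begin(), oc, false);
  Y.each_col() += bv;
  NumericVector y = make4(ox, oy, oz, oc);
  R_xlen_t nOut = (R_xlen_t)ox * oy * oz;
  for (int c = 0; c < oc; ++c)
    for (R_xlen_t o = 0; o < nOut; ++o) y[o + nOut * c] = Y(c, o);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericMatrix W, NumericVector dy,
                    int K, int S, int P) {
  IntegerVector xd = x.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int ic = xd[3], oc = yd[3];
  int ox = yd[0], oy = yd[1], oz = yd[2];
  R_xlen_t nOut = (R_xlen_t)ox * oy * oz;
  arma::mat cols = im2col3(x.begin(), xd.begin(), ic, K, S, P, ox, oy, oz);
  arma::mat Dy((double*)dy.begin(), nOut, oc, false);  // nOut x oc
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat dW = cols * Dy;                            // (K^3 ic) x oc
  arma::mat dcols = Wm * Dy.t();                       // (K^3 ic) x nOut
  NumericVector dx = make4(xd[0], xd[1], xd[2], ic);
  col2im3(dx.begin(), xd.begin(), ic, dcols, K, S, P, ox, oy, oz);
  arma::rowvec db = arma::sum(Dy, 0);
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transpose convolution: W has dims (K^3 * oc) x ic, output side = input * S
// (pad chosen as (K - S)/2 by the caller).
// [[Rcpp::export]]
NumericVector cpp_tconv3d_fwd(NumericVector x, NumericMatrix W, NumericVector b,
                              int K, int S, int P, int oc) {
  IntegerVector xd = x.attr("dim");
  int ic = xd[3];
  int ox = xd[0] * S, oy = xd[1] * S, oz = xd[2] * S;
  R_xlen_t nIn = (R_xlen_t)xd[0] * xd[1] * xd[2];
  arma::mat Xm((double*)x.begin(), nIn, ic, false);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat cols = Wm * Xm.t();                        // (K^3 oc) x nIn
  NumericVector y = make4(ox, oy, oz, oc);
  int yd[4] = {ox, oy, oz, oc};
  col2im3(y.begin(), yd, oc, cols, K, S, P, xd[0], xd[1], xd[2]);
  R_xlen_t nOut = (R_xlen_t)ox * oy * oz;
  for (int c = 0; c < oc; ++c) {
    double bc = b[c];
    for (R_xlen_t o = 0; o < nOut; ++o) y[o + nOut * c] += bc;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv3d_bwd(NumericVector x, NumericMatrix W, NumericVector dy,
                     int K, int S, int P) {
  IntegerVector xd = x.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int ic = xd[3], oc = yd[3];
  R_xlen_t nIn = (R_xlen_t)xd[0] * xd[1] * xd[2];
  arma::mat dcols = im2col3(dy.begin(), yd.begin(), oc, K, S, P,
                            xd[0], xd[1], xd[2]);    // (K^3 oc) x nIn
  arma::mat Xm((double*)x.begin(), nIn, ic, false);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat dXm = dcols.t() * Wm;                      // nIn x ic
  arma::mat dW = dcols * Xm;                           // (K^3 oc) x ic
  NumericVector dx = make4(xd[0], xd[1], xd[2], ic);
  std::copy(dXm.begin(), dXm.end(), dx.begin());
  R_xlen_t nOut = (R_xlen_t)yd[0] * yd[1] * yd[2];
  NumericVector db(oc);
  for (int c = 0; c < oc; ++c) {
    double s = 0;
    const double* p = dy.begin() + nOut * c;
    for (R_xlen_t o = 0; o < nOut; ++o) s += p[o];
    db[c] = s;
  }
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW), _["db"] = db);
}
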
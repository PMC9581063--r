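// GEMM cores for the 3x3x3 same-padded convolution.
//
// The patch ("im2col") matrix K has one row per voxel and column blocks of
// C_in channels per kernel offset, offsets enumerated with dx fastest over
// {-1,0,1}^3. Building K in C++ avoids repeated large allocations in the R
// heap; the matrix products go through BLAS via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// fill column block of K for one (offset, channel): contiguous x-runs
static void im2col_fill(const double* x, arma::mat& K,
                        int nx, int ny, int nz, int cin,
                        int dx, int dy, int dz, int col0) {
  const int n = nx * ny * nz;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (std::size_t)c * n;
    double* kc = K.colptr(col0 + c);
    for (int z = 0; z < nz; ++z) {
      int sz = z + dz;
      bool zok = sz >= 0 && sz < nz;
      for (int y = 0; y < ny; ++y) {
        int sy = y + dy;
        double* krow = kc + (std::size_t)(z * ny + y) * nx;
        if (!zok || sy < 0 || sy >= ny) {
          std::fill(krow, krow + nx, 0.0);
          continue;
        }
        const double* src = xc + (std::size_t)(sz * ny + sy) * nx;
        if (dx == 0) {
          std::copy(src, src + nx, krow);
        } else if (dx == 1) {
          std::copy(src + 1, src + nx, krow);
          krow[nx - 1] = 0.0;
        } else {  // dx == -1
          krow[0] = 0.0;
          std::copy(src, src + nx - 1, krow + 1);
        }
      }
    }
  }
}

static arma::mat build_patches(const double* x, int nx, int ny, int nz,
                               int cin) {
  const int n = nx * ny * nz;
  arma::mat K(n, 27 * cin);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o)
        im2col_fill(x, K, nx, ny, nz, cin, dx, dy, dz, o * cin);
  return K;
}

// weight array (27, cin, cout) -> GEMM matrix (27 * cin, cout),
// rows offset-major to match build_patches
static arma::mat weight_mat(const NumericVector& W, int cin, int cout) {
  arma::mat Wm(27 * cin, cout);
  const double* w = W.begin();
  for (int j = 0; j < cout; ++j)
    for (int c = 0; c < cin; ++c)
      for (int o = 0; o < 27; ++o)
        Wm(o * cin + c, j) = w[o + 27 * (c + (std::size_t)cin * j)];
  return Wm;
}

// [[Rcpp::export]]
List cpp_conv3d_forward(NumericVector x, NumericVector W, NumericVector b,
                        bool keep_patches) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = W.attr("dim");
  const int nx = dx[0], ny = dx[1], nz = dx[2], cin = dx[3];
  const int cout = dw[2];
  const int n = nx * ny * nz;
  // patch matrix lives outside the R heap (behind an external pointer when
  // cached) so repeated large temporaries do not thrash the R GC
  arma::mat* K = new arma::mat(n, 27 * cin);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dyo = -1; dyo <= 1; ++dyo)
      for (int dxo = -1; dxo <= 1; ++dxo, ++o)
        im2col_fill(x.begin(), *K, nx, ny, nz, cin, dxo, dyo, dz, o * cin);
  NumericVector out((R_xlen_t)n * cout);
  arma::mat Y(out.begin(), n, cout, false);
  Y = (*K) * weight_mat(W, cin, cout);
  Y.each_row() += arma::rowvec(b.begin(), cout);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  if (keep_patches) {
    XPtr<arma::mat> kp(K, true);
    return List::create(Named("y") = out, Named("k") = kp);
  }
  delete K;
  return List::create(Named("y") = out);
}

// [[Rcpp::export]]
List cpp_conv3d_backward(SEXP k, NumericVector dy, NumericVector W,
                         IntegerVector dims) {
  IntegerVector dw = W.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cin = dw[1], cout = dw[2];
  const int n = nx * ny * nz;
  const arma::mat dYm(dy.begin(), n, cout, false);

  // weight gradient: K(x)^T * dY, rearranged to (27, cin, cout)
  XPtr<arma::mat> kp(k);
  arma::mat dWm = kp->t() * dYm;         // (27*cin, cout), offset-major rows
  kp->reset();                           // backward is the cache's only consumer
  NumericVector dWout(27 * cin * cout);
  for (int j = 0; j < cout; ++j)
    for (int c = 0; c < cin; ++c)
      for (int o = 0; o < 27; ++o)
        dWout[o + 27 * (c + (std::size_t)cin * j)] = dWm(o * cin + c, j);
  dWout.attr("dim") = IntegerVector::create(27, cin, cout);

  // input gradient: correlation of dY with flipped transposed kernel
  arma::mat Wback(27 * cout, cin);
  const double* w = W.begin();
  for (int c = 0; c < cin; ++c)
    for (int j = 0; j < cout; ++j)
      for (int o = 0; o < 27; ++o)
        Wback(o * cout + j, c) = w[(26 - o) + 27 * (c + (std::size_t)cin * j)];
  arma::mat Kdy = build_patches(dy.begin(), nx, ny, nz, cout);
  NumericVector dxout((R_xlen_t)n * cin);
  arma::mat dXm(dxout.begin(), n, cin, false);
  dXm = Kdy * Wback;
  Kdy.reset();
  dxout.attr("dim") = IntegerVector::create(nx, ny, nz, cin);

  NumericVector db(cout);
  for (int j = 0; j < cout; ++j) db[j] = arma::accu(dYm.col(j));

  return List::create(Named("dx") = dxout, Named("dW") = dWout,
                      Named("db") = db);
}
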
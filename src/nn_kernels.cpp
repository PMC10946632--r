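// Low-level CPU kernels for the 3-D networks. Convolutions are computed in
// R as GEMM over an im2col expansion (BLAS does the heavy lifting); the
// kernels here provide the im2col/col2im reshuffles plus max-pooling and
// trilinear resampling with their adjoints.
//
// Tensor layout: column-major R arrays of dim c(X, Y, Z, C); linear index
// x + X*(y + Y*(z + Z*c)). The im2col matrix has one column per output
// voxel and k^3*Cin rows, ordered so that a flattened weight array of dim
// c(k, k, k, Cin, Cout) multiplies it directly.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static inline int out_extent(int n, int k, int pad, int stride, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export]]
IntegerVector nn_conv_out_dim(IntegerVector xdim, int k, int pad, int stride,
                              int dil) {
  return IntegerVector::create(out_extent(xdim[0], k, pad, stride, dil),
                               out_extent(xdim[1], k, pad, stride, dil),
                               out_extent(xdim[2], k, pad, stride, dil));
}

// valid output range [lo, hi) for one tap: 0 <= o*stride - pad + t*dil < n
static inline void tap_range(int n, int no, int pad, int stride, int dil,
                             int t, int &lo, int &hi) {
  int off = t * dil - pad;
  lo = 0;
  while (lo < no && lo * stride + off < 0) ++lo;
  hi = no;
  while (hi > lo && (hi - 1) * stride + off >= n) --hi;
}

// Column matrix layout: n_vox rows x (k^3*C) columns, so that consecutive
// output voxels are contiguous in memory and GEMM consumes it directly.
// [[Rcpp::export]]
NumericMatrix nn_im2col(NumericVector x, IntegerVector xdim, int k, int pad,
                        int stride, int dil) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int Xo = out_extent(X, k, pad, stride, dil);
  const int Yo = out_extent(Y, k, pad, stride, dil);
  const int Zo = out_extent(Z, k, pad, stride, dil);
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("conv3d: output collapsed to zero extent");
  const R_xlen_t nvox = R_xlen_t(Xo) * Yo * Zo;
  const int ntap = k * k * k * C;
  NumericMatrix col(nvox, ntap);
  const double *px = x.begin();
  double *pc = col.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + R_xlen_t(X) * Y * Z * c;
    for (int kz = 0; kz < k; ++kz) {
      int zlo, zhi; tap_range(Z, Zo, pad, stride, dil, kz, zlo, zhi);
      for (int ky = 0; ky < k; ++ky) {
        int ylo, yhi; tap_range(Y, Yo, pad, stride, dil, ky, ylo, yhi);
        for (int kx = 0; kx < k; ++kx) {
          int xlo, xhi; tap_range(X, Xo, pad, stride, dil, kx, xlo, xhi);
          const R_xlen_t tap = kx + k * (ky + k * (kz + R_xlen_t(k) * c));
          double *ct = pc + nvox * tap;
          const int ox = kx * dil - pad, oy = ky * dil - pad,
                    oz = kz * dil - pad;
          for (int zo = zlo; zo < zhi; ++zo) {
            const int zi = zo * stride + oz;
            for (int yo = ylo; yo < yhi; ++yo) {
              const int yi = yo * stride + oy;
              const double *xr =
                  xc + R_xlen_t(X) * (yi + R_xlen_t(Y) * zi) + ox;
              double *cr = ct + xlo + R_xlen_t(Xo) * (yo + R_xlen_t(Yo) * zo);
              if (stride == 1) {
                const double *xs = xr + xlo;
                for (int xo = 0; xo < xhi - xlo; ++xo) cr[xo] = xs[xo];
              } else {
                for (int xo = xlo; xo < xhi; ++xo)
                  cr[xo - xlo] = xr[xo * stride];
              }
            }
          }
        }
      }
    }
  }
  return col;
}

// adjoint of im2col: scatter-add the column matrix back into image layout
// [[Rcpp::export]]
NumericVector nn_col2im(NumericMatrix col, IntegerVector xdim, int k, int pad,
                        int stride, int dil) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int Xo = out_extent(X, k, pad, stride, dil);
  const int Yo = out_extent(Y, k, pad, stride, dil);
  const int Zo = out_extent(Z, k, pad, stride, dil);
  const R_xlen_t nvox = R_xlen_t(Xo) * Yo * Zo;
  NumericVector x(R_xlen_t(X) * Y * Z * C);
  double *px = x.begin();
  const double *pc = col.begin();
  for (int c = 0; c < C; ++c) {
    double *xc = px + R_xlen_t(X) * Y * Z * c;
    for (int kz = 0; kz < k; ++kz) {
      int zlo, zhi; tap_range(Z, Zo, pad, stride, dil, kz, zlo, zhi);
      for (int ky = 0; ky < k; ++ky) {
        int ylo, yhi; tap_range(Y, Yo, pad, stride, dil, ky, ylo, yhi);
        for (int kx = 0; kx < k; ++kx) {
          int xlo, xhi; tap_range(X, Xo, pad, stride, dil, kx, xlo, xhi);
          const R_xlen_t tap = kx + k * (ky + k * (kz + R_xlen_t(k) * c));
          const double *ct = pc + nvox * tap;
          const int ox = kx * dil - pad, oy = ky * dil - pad,
                    oz = kz * dil - pad;
          for (int zo = zlo; zo < zhi; ++zo) {
            const int zi = zo * stride + oz;
            for (int yo = ylo; yo < yhi; ++yo) {
              const int yi = yo * stride + oy;
              double *xr = xc + R_xlen_t(X) * (yi + R_xlen_t(Y) * zi) + ox;
              const double *cr = ct + xlo + R_xlen_t(Xo) * (yo + R_xlen_t(Yo) * zo);
              if (stride == 1) {
                double *xs = xr + xlo;
                for (int xo = 0; xo < xhi - xlo; ++xo) xs[xo] += cr[xo];
              } else {
                for (int xo = xlo; xo < xhi; ++xo)
                  xr[xo * stride] += cr[xo - xlo];
              }
            }
          }
        }
      }
    }
  }
  return x;
}

// 2x2x2 max pooling, stride 2; argmax indices (0-based into input) kept for
// the backward scatter.
// [[Rcpp::export]]
List nn_maxpool3d_fw(NumericVector x, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  if (X % 2 || Y % 2 || Z % 2) stop("maxpool3d: spatial extents must be even");
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector y(R_xlen_t(Xo) * Yo * Zo * C);
  IntegerVector idx(y.size());
  const double *px = x.begin();
  double *py = y.begin();
  int *pid = idx.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int xo = 0; xo < Xo; ++xo, ++o) {
          double best = R_NegInf;
          R_xlen_t bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const R_xlen_t ii =
                    (2 * xo + dx) +
                    R_xlen_t(X) * ((2 * yo + dy) +
                                   R_xlen_t(Y) * ((2 * zo + dz) + R_xlen_t(Z) * c));
                if (px[ii] > best) { best = px[ii]; bi = ii; }
              }
          py[o] = best;
          pid[o] = (int)bi;
        }
  return List::create(_["y"] = y, _["idx"] = idx,
                      _["dim"] = IntegerVector::create(Xo, Yo, Zo, C));
}

// [[Rcpp::export]]
NumericVector nn_maxpool3d_bw(IntegerVector idx, NumericVector gy,
                              R_xlen_t xlen) {
  NumericVector gx(xlen);
  const int *pid = idx.begin();
  const double *pgy = gy.begin();
  double *pgx = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) pgx[pid[i]] += pgy[i];
  return gx;
}

struct LinW { int i0, i1; double w0, w1; };

static void lin_weights(int n_in, int n_out, std::vector<LinW> &t) {
  // half-pixel-centre convention, clamped at the borders
  t.resize(n_out);
  const double scale = double(n_in) / double(n_out);
  for (int o = 0; o < n_out; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int i0 = (int)std::floor(s);
    int i1 = std::min(i0 + 1, n_in - 1);
    double f = s - i0;
    t[o] = {i0, i1, 1.0 - f, f};
  }
}

// [[Rcpp::export]]
NumericVector nn_upsample3d_fw(NumericVector x, IntegerVector xdim,
                               IntegerVector odim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int Xo = odim[0], Yo = odim[1], Zo = odim[2];
  std::vector<LinW> tx, ty, tz;
  lin_weights(X, Xo, tx); lin_weights(Y, Yo, ty); lin_weights(Z, Zo, tz);
  NumericVector y(R_xlen_t(Xo) * Yo * Zo * C);
  const double *px = x.begin();
  double *py = y.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    const double *xc = px + R_xlen_t(X) * Y * Z * c;
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int xo = 0; xo < Xo; ++xo, ++o) {
          const LinW &ax = tx[xo], &ay = ty[yo], &az = tz[zo];
          double v = 0.0;
          for (int dz = 0; dz < 2; ++dz) {
            const int zi = dz ? az.i1 : az.i0;
            const double wz = dz ? az.w1 : az.w0;
            if (wz == 0.0) continue;
            for (int dy = 0; dy < 2; ++dy) {
              const int yi = dy ? ay.i1 : ay.i0;
              const double wy = dy ? ay.w1 : ay.w0;
              if (wy == 0.0) continue;
              const double *row = xc + R_xlen_t(X) * (yi + R_xlen_t(Y) * zi);
              v += wz * wy * (ax.w0 * row[ax.i0] + ax.w1 * row[ax.i1]);
            }
          }
          py[o] = v;
        }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample3d_bw(NumericVector gy, IntegerVector odim,
                               IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int Xo = odim[0], Yo = odim[1], Zo = odim[2];
  std::vector<LinW> tx, ty, tz;
  lin_weights(X, Xo, tx); lin_weights(Y, Yo, ty); lin_weights(Z, Zo, tz);
  NumericVector gx(R_xlen_t(X) * Y * Z * C);
  const double *pgy = gy.begin();
  double *pgx = gx.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    double *xc = pgx + R_xlen_t(X) * Y * Z * c;
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int xo = 0; xo < Xo; ++xo, ++o) {
          const LinW &ax = tx[xo], &ay = ty[yo], &az = tz[zo];
          const double g = pgy[o];
          if (g == 0.0) continue;
          for (int dz = 0; dz < 2; ++dz) {
            const int zi = dz ? az.i1 : az.i0;
            const double wz = dz ? az.w1 : az.w0;
            if (wz == 0.0) continue;
            for (int dy = 0; dy < 2; ++dy) {
              const int yi = dy ? ay.i1 : ay.i0;
              const double wy = dy ? ay.w1 : ay.w0;
              if (wy == 0.0) continue;
              double *row = xc + R_xlen_t(X) * (yi + R_xlen_t(Y) * zi);
              row[ax.i0] += g * wz * wy * ax.w0;
              row[ax.i1] += g * wz * wy * ax.w1;
            }
          }
        }
  }
  return gx;
}
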
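// 3D convolution kernels for the residual age regressor.
//
// Layout conventions (all column-major, matching R arrays):
//   x  : (X, Y, Z, C_in, N)
//   w  : (kx*ky*kz*C_in, C_out)  -- kernel x fastest, then y, z, channel
//   y  : (OX, OY, OZ, C_out, N)
// Convolution is cross-correlation (the deep-learning convention) with
// zero padding. Forward and backward both go through an explicit
// vol2col/col2vol buffer and a GEMM.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather the patch matrix for one sample: (kx*ky*kz*Cin) x (OX*OY*OZ).
static void vol2col(const double* x, int X, int Y, int Z, int C,
                    int k, int stride, int pad,
                    int OX, int OY, int OZ, arma::mat& col) {
  const long plane = (long)X * Y;
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        long c_idx = (long)ox + (long)OX * (oy + (long)OY * oz);
        double* dst = col.colptr(c_idx);
        int bx = ox * stride - pad, by = oy * stride - pad,
            bz = oz * stride - pad;
        long r = 0;
        for (int c = 0; c < C; ++c) {
          const double* xc = x + (long)c * plane * Z;
          for (int kz = 0; kz < k; ++kz) {
            int iz = bz + kz;
            for (int ky = 0; ky < k; ++ky) {
              int iy = by + ky;
              for (int kx = 0; kx < k; ++kx, ++r) {
                int ix = bx + kx;
                dst[r] = (ix >= 0 && ix < X && iy >= 0 && iy < Y &&
                          iz >= 0 && iz < Z)
                  ? xc[ix + (long)X * (iy + (long)Y * iz)] : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add the patch matrix back into a gradient volume.
static void col2vol(const arma::mat& col, int X, int Y, int Z, int C,
                    int k, int stride, int pad,
                    int OX, int OY, int OZ, double* dx) {
  const long plane = (long)X * Y;
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        long c_idx = (long)ox + (long)OX * (oy + (long)OY * oz);
        const double* src = col.colptr(c_idx);
        int bx = ox * stride - pad, by = oy * stride - pad,
            bz = oz * stride - pad;
        long r = 0;
        for (int c = 0; c < C; ++c) {
          double* xc = dx + (long)c * plane * Z;
          for (int kz = 0; kz < k; ++kz) {
            int iz = bz + kz;
            for (int ky = 0; ky < k; ++ky) {
              int iy = by + ky;
              for (int kx = 0; kx < k; ++kx, ++r) {
                int ix = bx + kx;
                if (ix >= 0 && ix < X && iy >= 0 && iy < Y &&
                    iz >= 0 && iz < Z)
                  xc[ix + (long)X * (iy + (long)Y * iz)] += src[r];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericMatrix w,
                         int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  int OX = out_size(X, k, stride, pad), OY = out_size(Y, k, stride, pad),
      OZ = out_size(Z, k, stride, pad);
  int Cout = w.ncol();
  long patch = (long)k * k * k * C, OV = (long)OX * OY * OZ;
  if ((long)w.nrow() != patch) stop("weight rows do not match patch size");
  NumericVector y(OV * Cout * (long)N);
  y.attr("dim") = IntegerVector::create(OX, OY, OZ, Cout, N);
  arma::mat W(w.begin(), patch, Cout, false, true);
  arma::mat col(patch, OV);
  const long xstride = (long)X * Y * Z * C, ystride = OV * Cout;
  for (int n = 0; n < N; ++n) {
    vol2col(x.begin() + n * xstride, X, Y, Z, C, k, stride, pad,
            OX, OY, OZ, col);
    arma::mat out(y.begin() + n * ystride, OV, Cout, false, true);
    out = col.t() * W;
  }
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  int OX = out_size(X, k, stride, pad), OY = out_size(Y, k, stride, pad),
      OZ = out_size(Z, k, stride, pad);
  int Cout = w.ncol();
  long patch = (long)k * k * k * C, OV = (long)OX * OY * OZ;
  arma::mat W(w.begin(), patch, Cout, false, true);
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  NumericMatrix dw(patch, Cout);
  arma::mat dW(dw.begin(), patch, Cout, false, true);
  arma::mat col(patch, OV);
  const long xstride = (long)X * Y * Z * C, ystride = OV * Cout;
  for (int n = 0; n < N; ++n) {
    vol2col(x.begin() + n * xstride, X, Y, Z, C, k, stride, pad,
            OX, OY, OZ, col);
    arma::mat dYn(const_cast<double*>(dy.begin()) + n * ystride,
                  OV, Cout, false, true);
    dW += col * dYn;
    arma::mat dcol = W * dYn.t();
    col2vol(dcol, X, Y, Z, C, k, stride, pad, OX, OY, OZ,
            dx.begin() + n * xstride);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
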
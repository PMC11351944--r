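// 3D convolution primitives (im2col + GEMM), used by the encoder-decoder
// network. Volumes are column-major R arrays of dim (d1, d2, d3, C).
// Kernels are cubic (k in {1,3}) with "same"-style zero padding p=(k-1)/2
// and isotropic stride. Weight matrices have dim (k^3 * Cin, Cout) with the
// kernel offset index varying fastest within each input channel block.
// im2col buffers are built one z-slab at a time, column-by-column so both
// the source reads and the buffer writes stay contiguous, and peak memory
// stays bounded for full-width networks on whole patches.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int d, int k, int p, int s) {
  return (d + 2 * p - k) / s + 1;
}

static inline int slab_slices(int o1, int o2) {
  int target_rows = 8192;
  int per_slice = o1 * o2;
  int n = target_rows / per_slice;
  return n < 1 ? 1 : n;
}

// Fill `cols` (nz*o1*o2 x k^3*Cin) for output z-slices [z0, z0+nz).
static void im2col_slab(const double* x, int d1, int d2, int d3, int cin,
                        int k, int p, int s, int o1, int o2,
                        int z0, int nz, arma::mat& cols) {
  const int k3 = k * k * k;
  const std::size_t plane = (std::size_t)d1 * d2;
  const std::size_t volsz = plane * d3;
  cols.zeros();
  for (int c = 0; c < cin; ++c) {
    for (int k3i = 0; k3i < k; ++k3i) {
      for (int k2i = 0; k2i < k; ++k2i) {
        for (int k1i = 0; k1i < k; ++k1i) {
          int j = (k1i + k * (k2i + k * k3i)) + k3 * c;
          double* col = cols.colptr(j);
          for (int zz = 0; zz < nz; ++zz) {
            int z = (z0 + zz) * s - p + k3i;
            if (z < 0 || z >= d3) continue;
            for (int i2 = 0; i2 < o2; ++i2) {
              int y = i2 * s - p + k2i;
              if (y < 0 || y >= d2) continue;
              double* dst = col + (std::size_t)zz * o1 * o2 + (std::size_t)i2 * o1;
              const double* src = x + volsz * c + plane * z + (std::size_t)d1 * y;
              int start = k1i - p;
              if (s == 1) {
                int lo = start < 0 ? -start : 0;
                int hi = (start + o1 > d1) ? d1 - start : o1;
                for (int i1 = lo; i1 < hi; ++i1) dst[i1] = src[start + i1];
              } else {
                for (int i1 = 0; i1 < o1; ++i1) {
                  int xx = start + i1 * s;
                  if (xx >= 0 && xx < d1) dst[i1] = src[xx];
                }
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, IntegerVector dims,
                                 NumericMatrix w, NumericVector bias,
                                 int k, int stride) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  int p = (k - 1) / 2;
  int o1 = out_dim(d1, k, p, stride), o2 = out_dim(d2, k, p, stride),
      o3 = out_dim(d3, k, p, stride);
  int cout = w.ncol();
  std::size_t n_out = (std::size_t)o1 * o2 * o3;
  NumericVector y(n_out * cout);
  arma::mat W(w.begin(), w.nrow(), cout, false);
  arma::mat Y(y.begin(), n_out, cout, false);
  int nz_max = slab_slices(o1, o2);
  arma::mat cols;
  for (int z0 = 0; z0 < o3; z0 += nz_max) {
    int nz = std::min(nz_max, o3 - z0);
    std::size_t rows = (std::size_t)nz * o1 * o2;
    if (cols.n_rows != rows) cols.set_size(rows, w.nrow());
    im2col_slab(x.begin(), d1, d2, d3, cin, k, p, stride, o1, o2, z0, nz, cols);
    std::size_t row0 = (std::size_t)z0 * o1 * o2;
    Y.rows(row0, row0 + rows - 1) = cols * W;
  }
  for (int c = 0; c < cout; ++c) {
    double b = bias[c];
    double* col = y.begin() + n_out * (std::size_t)c;
    for (std::size_t i = 0; i < n_out; ++i) col[i] += b;
  }
  y.attr("dim") = IntegerVector::create(o1, o2, o3, cout);
  return y;
}

// Scatter-add one slab of dcols (nz*o1*o2 x k^3*Cin) back into dx (col2im).
static void col2im_slab(double* dx, int d1, int d2, int d3, int cin,
                        int k, int p, int s, int o1, int o2,
                        int z0, int nz, const arma::mat& dcols) {
  const int k3 = k * k * k;
  const std::size_t plane = (std::size_t)d1 * d2;
  const std::size_t volsz = plane * d3;
  for (int c = 0; c < cin; ++c) {
    for (int k3i = 0; k3i < k; ++k3i) {
      for (int k2i = 0; k2i < k; ++k2i) {
        for (int k1i = 0; k1i < k; ++k1i) {
          int j = (k1i + k * (k2i + k * k3i)) + k3 * c;
          const double* col = dcols.colptr(j);
          for (int zz = 0; zz < nz; ++zz) {
            int z = (z0 + zz) * s - p + k3i;
            if (z < 0 || z >= d3) continue;
            for (int i2 = 0; i2 < o2; ++i2) {
              int y = i2 * s - p + k2i;
              if (y < 0 || y >= d2) continue;
              const double* srcc = col + (std::size_t)zz * o1 * o2 + (std::size_t)i2 * o1;
              double* dst = dx + volsz * c + plane * z + (std::size_t)d1 * y;
              int start = k1i - p;
              if (s == 1) {
                int lo = start < 0 ? -start : 0;
                int hi = (start + o1 > d1) ? d1 - start : o1;
                for (int i1 = lo; i1 < hi; ++i1) dst[start + i1] += srcc[i1];
              } else {
                for (int i1 = 0; i1 < o1; ++i1) {
                  int xx = start + i1 * s;
                  if (xx >= 0 && xx < d1) dst[xx] += srcc[i1];
                }
              }
            }
          }
        }
      }
    }
  }
}

// Gradient w.r.t. the input volume: dY %*% t(W) pushed back through the
// im2col map.
// [[Rcpp::export]]
NumericVector cpp_conv3d_backward_x(NumericVector dy, IntegerVector dims,
                                    NumericMatrix w, int k, int stride) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  int p = (k - 1) / 2;
  int o1 = out_dim(d1, k, p, stride), o2 = out_dim(d2, k, p, stride),
      o3 = out_dim(d3, k, p, stride);
  int cout = w.ncol();
  std::size_t n_out = (std::size_t)o1 * o2 * o3;
  const std::size_t volsz = (std::size_t)d1 * d2 * d3;
  NumericVector dx(volsz * cin);
  arma::mat W(w.begin(), w.nrow(), cout, false);
  arma::mat dY(dy.begin(), n_out, cout, false);
  int nz_max = slab_slices(o1, o2);
  for (int z0 = 0; z0 < o3; z0 += nz_max) {
    int nz = std::min(nz_max, o3 - z0);
    std::size_t rows = (std::size_t)nz * o1 * o2;
    std::size_t row0 = (std::size_t)z0 * o1 * o2;
    arma::mat dcols = dY.rows(row0, row0 + rows - 1) * W.t();
    col2im_slab(dx.begin(), d1, d2, d3, cin, k, p, stride, o1, o2, z0, nz,
                dcols);
  }
  dx.attr("dim") = IntegerVector::create(d1, d2, d3, cin);
  return dx;
}

// Gradients w.r.t. weights and bias: dW = t(im2col(x)) %*% dY, db = colSums(dY).
// [[Rcpp::export]]
List cpp_conv3d_backward_w(NumericVector x, IntegerVector dims,
                           NumericVector dy, int cout, int k, int stride) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  int p = (k - 1) / 2;
  int o1 = out_dim(d1, k, p, stride), o2 = out_dim(d2, k, p, stride),
      o3 = out_dim(d3, k, p, stride);
  int k3 = k * k * k;
  std::size_t n_out = (std::size_t)o1 * o2 * o3;
  arma::mat dY(dy.begin(), n_out, cout, false);
  arma::mat dW((std::size_t)k3 * cin, cout, arma::fill::zeros);
  int nz_max = slab_slices(o1, o2);
  arma::mat cols;
  for (int z0 = 0; z0 < o3; z0 += nz_max) {
    int nz = std::min(nz_max, o3 - z0);
    std::size_t rows = (std::size_t)nz * o1 * o2;
    std::size_t row0 = (std::size_t)z0 * o1 * o2;
    if (cols.n_rows != rows) cols.set_size(rows, (std::size_t)k3 * cin);
    im2col_slab(x.begin(), d1, d2, d3, cin, k, p, stride, o1, o2, z0, nz, cols);
    dW += cols.t() * dY.rows(row0, row0 + rows - 1);
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}
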
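// Low-level 3D convolution kernels for the segmentation network.
//
// Tensor layout: R arrays with dim = c(n1, n2, n3, C) (column-major, so each
// channel is one contiguous block of n1*n2*n3 doubles).  Stride-1 "same"
// convolutions use im2col over z-slabs (bounded scratch memory) followed by a
// single BLAS GEMM; the 2x2x2 stride-2 resampling convolutions have
// non-overlapping receptive fields and reduce to one GEMM each.
//
// Weight layouts (match the R side):
//   conv3  : matrix (Cin*K^3, Cout), row q = di + K*(dj + K*(dk + K*cin))
//   down2  : matrix (Cin*8,   Cout), row q = di + 2*(dj + 2*(dk + 2*cin))
//   up2    : matrix (Cin, Cout*8),   col q = di + 2*(dj + 2*(dk + 2*cout))

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (n1, n2, n3, channels)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Fill column q of the im2col matrix A (nslab_vox rows) for kernel offset
// (di, dj, dk) of channel cin, output slab [k0, k1).
static void im2col_fill(const double *xc, double *col,
                        int n1, int n2, int n3,
                        int di, int dj, int dk, int pad,
                        int k0, int k1) {
  const int ilo = std::max(0, pad - di);
  const int ihi = std::min(n1, n1 + pad - di);
  for (int k = k0; k < k1; ++k) {
    const int sk = k + dk - pad;
    for (int j = 0; j < n2; ++j) {
      const int sj = j + dj - pad;
      double *dst = col + (static_cast<size_t>(k - k0) * n2 + j) * n1;
      if (sk < 0 || sk >= n3 || sj < 0 || sj >= n2 || ilo >= ihi) {
        std::memset(dst, 0, sizeof(double) * n1);
        continue;
      }
      const double *src = xc + (static_cast<size_t>(sk) * n2 + sj) * n1 + (di - pad);
      if (ilo > 0) std::memset(dst, 0, sizeof(double) * ilo);
      std::memcpy(dst + ilo, src + ilo, sizeof(double) * (ihi - ilo));
      if (ihi < n1) std::memset(dst + ihi, 0, sizeof(double) * (n1 - ihi));
    }
  }
}

// Scatter-add column q of Ga back into gradient channel gxc (col2im).
static void col2im_add(double *gxc, const double *col,
                       int n1, int n2, int n3,
                       int di, int dj, int dk, int pad,
                       int k0, int k1) {
  const int ilo = std::max(0, pad - di);
  const int ihi = std::min(n1, n1 + pad - di);
  if (ilo >= ihi) return;
  for (int k = k0; k < k1; ++k) {
    const int sk = k + dk - pad;
    if (sk < 0 || sk >= n3) continue;
    for (int j = 0; j < n2; ++j) {
      const int sj = j + dj - pad;
      if (sj < 0 || sj >= n2) continue;
      const double *src = col + (static_cast<size_t>(k - k0) * n2 + j) * n1;
      double *dst = gxc + (static_cast<size_t>(sk) * n2 + sj) * n1 + (di - pad);
      for (int i = ilo; i < ihi; ++i) dst[i] += src[i];
    }
  }
}

static int slab_slices(int n1, int n2, int rows) {
  // keep the im2col scratch under ~128 MB
  const double limit = 16e6;
  int s = static_cast<int>(limit / (static_cast<double>(n1) * n2 * rows));
  return std::max(1, s);
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fw(NumericVector x, NumericMatrix w, NumericVector b,
                           int K) {
  int d[4]; get_dims4(x, d);
  const int n1 = d[0], n2 = d[1], n3 = d[2], Cin = d[3];
  const int K3 = K * K * K, R = w.nrow(), Cout = w.ncol();
  if (R != Cin * K3) stop("weight rows != Cin*K^3");
  if (b.size() != Cout) stop("bias length != Cout");
  const int pad = (K - 1) / 2;
  const size_t n123 = static_cast<size_t>(n1) * n2 * n3;

  NumericVector y(n123 * Cout);
  y.attr("dim") = IntegerVector::create(n1, n2, n3, Cout);
  const arma::mat W(const_cast<double *>(w.begin()), R, Cout, false, true);
  const arma::rowvec bv(const_cast<double *>(b.begin()), Cout, false, true);

  const int step = slab_slices(n1, n2, R);
  for (int k0 = 0; k0 < n3; k0 += step) {
    const int k1 = std::min(n3, k0 + step);
    const size_t nv = static_cast<size_t>(n1) * n2 * (k1 - k0);
    arma::mat A(nv, R);
    for (int cin = 0; cin < Cin; ++cin) {
      const double *xc = x.begin() + cin * n123;
      for (int dk = 0; dk < K; ++dk)
        for (int dj = 0; dj < K; ++dj)
          for (int di = 0; di < K; ++di) {
            const int q = di + K * (dj + K * (dk + K * cin));
            im2col_fill(xc, A.colptr(q), n1, n2, n3, di, dj, dk, pad, k0, k1);
          }
    }
    arma::mat Y = A * W;
    Y.each_row() += bv;
    for (int co = 0; co < Cout; ++co)
      std::memcpy(y.begin() + co * n123 + static_cast<size_t>(k0) * n1 * n2,
                  Y.colptr(co), sizeof(double) * nv);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_bw(NumericVector x, NumericMatrix w, NumericVector gy, int K) {
  int d[4]; get_dims4(x, d);
  const int n1 = d[0], n2 = d[1], n3 = d[2], Cin = d[3];
  const int K3 = K * K * K, R = w.nrow(), Cout = w.ncol();
  const int pad = (K - 1) / 2;
  const size_t n123 = static_cast<size_t>(n1) * n2 * n3;

  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericMatrix gw(R, Cout);
  NumericVector gb(Cout);
  const arma::mat W(const_cast<double *>(w.begin()), R, Cout, false, true);
  arma::mat GW(gw.begin(), R, Cout, false, true);
  arma::vec GB(gb.begin(), Cout, false, true);

  const int step = slab_slices(n1, n2, R);
  for (int k0 = 0; k0 < n3; k0 += step) {
    const int k1 = std::min(n3, k0 + step);
    const size_t nv = static_cast<size_t>(n1) * n2 * (k1 - k0);
    arma::mat A(nv, R);
    for (int cin = 0; cin < Cin; ++cin) {
      const double *xc = x.begin() + cin * n123;
      for (int dk = 0; dk < K; ++dk)
        for (int dj = 0; dj < K; ++dj)
          for (int di = 0; di < K; ++di) {
            const int q = di + K * (dj + K * (dk + K * cin));
            im2col_fill(xc, A.colptr(q), n1, n2, n3, di, dj, dk, pad, k0, k1);
          }
    }
    arma::mat Gy(nv, Cout);
    for (int co = 0; co < Cout; ++co)
      std::memcpy(Gy.colptr(co),
                  gy.begin() + co * n123 + static_cast<size_t>(k0) * n1 * n2,
                  sizeof(double) * nv);
    GW += A.t() * Gy;
    GB += arma::sum(Gy, 0).t();
    arma::mat Ga = Gy * W.t();
    for (int cin = 0; cin < Cin; ++cin) {
      double *gxc = gx.begin() + cin * n123;
      for (int dk = 0; dk < K; ++dk)
        for (int dj = 0; dj < K; ++dj)
          for (int di = 0; di < K; ++di) {
            const int q = di + K * (dj + K * (dk + K * cin));
            col2im_add(gxc, Ga.colptr(q), n1, n2, n3, di, dj, dk, pad, k0, k1);
          }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Gather 2x2x2 non-overlapping blocks: A(v, q) = x(2i+di, 2j+dj, 2k+dk, cin)
static void blocks_gather(const NumericVector &x, arma::mat &A,
                          int n1, int n2, int n3, int Cin) {
  const int m1 = n1 / 2, m2 = n2 / 2, m3 = n3 / 2;
  const size_t n123 = static_cast<size_t>(n1) * n2 * n3;
  for (int cin = 0; cin < Cin; ++cin) {
    const double *xc = x.begin() + cin * n123;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const int q = di + 2 * (dj + 2 * (dk + 2 * cin));
          double *col = A.colptr(q);
          for (int k = 0; k < m3; ++k)
            for (int j = 0; j < m2; ++j) {
              const double *src =
                  xc + (static_cast<size_t>(2 * k + dk) * n2 + 2 * j + dj) * n1 + di;
              double *dst = col + (static_cast<size_t>(k) * m2 + j) * m1;
              for (int i = 0; i < m1; ++i) dst[i] = src[2 * i];
            }
        }
  }
}

static void blocks_scatter_add(NumericVector &gx, const arma::mat &Ga,
                               int n1, int n2, int n3, int Cin) {
  const int m1 = n1 / 2, m2 = n2 / 2, m3 = n3 / 2;
  const size_t n123 = static_cast<size_t>(n1) * n2 * n3;
  for (int cin = 0; cin < Cin; ++cin) {
    double *gxc = gx.begin() + cin * n123;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const int q = di + 2 * (dj + 2 * (dk + 2 * cin));
          const double *col = Ga.colptr(q);
          for (int k = 0; k < m3; ++k)
            for (int j = 0; j < m2; ++j) {
              double *dst =
                  gxc + (static_cast<size_t>(2 * k + dk) * n2 + 2 * j + dj) * n1 + di;
              const double *src = col + (static_cast<size_t>(k) * m2 + j) * m1;
              for (int i = 0; i < m1; ++i) dst[2 * i] += src[i];
            }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_down2_fw(NumericVector x, NumericMatrix w, NumericVector b) {
  int d[4]; get_dims4(x, d);
  const int n1 = d[0], n2 = d[1], n3 = d[2], Cin = d[3];
  if (n1 % 2 || n2 % 2 || n3 % 2) stop("down2: dims must be even");
  const int Cout = w.ncol();
  if (w.nrow() != Cin * 8) stop("down2: weight rows != Cin*8");
  const int m1 = n1 / 2, m2 = n2 / 2, m3 = n3 / 2;
  const size_t mv = static_cast<size_t>(m1) * m2 * m3;

  arma::mat A(mv, Cin * 8);
  blocks_gather(x, A, n1, n2, n3, Cin);
  const arma::mat W(const_cast<double *>(w.begin()), Cin * 8, Cout, false, true);
  const arma::rowvec bv(const_cast<double *>(b.begin()), Cout, false, true);
  arma::mat Y = A * W;
  Y.each_row() += bv;

  NumericVector y(mv * Cout);
  y.attr("dim") = IntegerVector::create(m1, m2, m3, Cout);
  std::memcpy(y.begin(), Y.memptr(), sizeof(double) * mv * Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_down2_bw(NumericVector x, NumericMatrix w, NumericVector gy) {
  int d[4]; get_dims4(x, d);
  const int n1 = d[0], n2 = d[1], n3 = d[2], Cin = d[3];
  const int Cout = w.ncol();
  const int m1 = n1 / 2, m2 = n2 / 2, m3 = n3 / 2;
  const size_t mv = static_cast<size_t>(m1) * m2 * m3;

  arma::mat A(mv, Cin * 8);
  blocks_gather(x, A, n1, n2, n3, Cin);
  const arma::mat W(const_cast<double *>(w.begin()), Cin * 8, Cout, false, true);
  const arma::mat Gy(const_cast<double *>(gy.begin()), mv, Cout, false, true);

  NumericMatrix gw(Cin * 8, Cout);
  arma::mat GW(gw.begin(), Cin * 8, Cout, false, true);
  GW = A.t() * Gy;
  NumericVector gb(Cout);
  arma::vec GB(gb.begin(), Cout, false, true);
  GB = arma::sum(Gy, 0).t();

  arma::mat Ga = Gy * W.t();
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  blocks_scatter_add(gx, Ga, n1, n2, n3, Cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_up2_fw(NumericVector x, NumericMatrix w, NumericVector b) {
  int d[4]; get_dims4(x, d);
  const int m1 = d[0], m2 = d[1], m3 = d[2], Cin = d[3];
  const int Cout = w.ncol() / 8;
  if (w.nrow() != Cin || w.ncol() != Cout * 8) stop("up2: bad weight shape");
  const size_t mv = static_cast<size_t>(m1) * m2 * m3;
  const int n1 = 2 * m1, n2 = 2 * m2, n3 = 2 * m3;
  const size_t n123 = static_cast<size_t>(n1) * n2 * n3;

  const arma::mat X(const_cast<double *>(x.begin()), mv, Cin, false, true);
  const arma::mat W(const_cast<double *>(w.begin()), Cin, Cout * 8, false, true);
  arma::mat B = X * W;  // (mv, Cout*8)

  NumericVector y(n123 * Cout);
  y.attr("dim") = IntegerVector::create(n1, n2, n3, Cout);
  for (int co = 0; co < Cout; ++co) {
    double *yc = y.begin() + co * n123;
    const double bc = b[co];
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const int q = di + 2 * (dj + 2 * (dk + 2 * co));
          const double *col = B.colptr(q);
          for (int k = 0; k < m3; ++k)
            for (int j = 0; j < m2; ++j) {
              double *dst =
                  yc + (static_cast<size_t>(2 * k + dk) * n2 + 2 * j + dj) * n1 + di;
              const double *src = col + (static_cast<size_t>(k) * m2 + j) * m1;
              for (int i = 0; i < m1; ++i) dst[2 * i] = src[i] + bc;
            }
        }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_up2_bw(NumericVector x, NumericMatrix w, NumericVector gy) {
  int d[4]; get_dims4(x, d);
  const int m1 = d[0], m2 = d[1], m3 = d[2], Cin = d[3];
  const int Cout = w.ncol() / 8;
  const size_t mv = static_cast<size_t>(m1) * m2 * m3;
  const int n1 = 2 * m1, n2 = 2 * m2, n3 = 2 * m3;
  const size_t n123 = static_cast<size_t>(n1) * n2 * n3;

  // gather gy into block layout Gb (mv, Cout*8)
  arma::mat Gb(mv, Cout * 8);
  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double *gyc = gy.begin() + co * n123;
    double acc = 0.0;
    for (size_t t = 0; t < n123; ++t) acc += gyc[t];
    gb[co] = acc;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const int q = di + 2 * (dj + 2 * (dk + 2 * co));
          double *col = Gb.colptr(q);
          for (int k = 0; k < m3; ++k)
            for (int j = 0; j < m2; ++j) {
              const double *src =
                  gyc + (static_cast<size_t>(2 * k + dk) * n2 + 2 * j + dj) * n1 + di;
              double *dst = col + (static_cast<size_t>(k) * m2 + j) * m1;
              for (int i = 0; i < m1; ++i) dst[i] = src[2 * i];
            }
        }
  }

  const arma::mat X(const_cast<double *>(x.begin()), mv, Cin, false, true);
  const arma::mat W(const_cast<double *>(w.begin()), Cin, Cout * 8, false, true);
  NumericMatrix gw(Cin, Cout * 8);
  arma::mat GW(gw.begin(), Cin, Cout * 8, false, true);
  GW = X.t() * Gb;

  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  arma::mat GX(gx.begin(), mv, Cin, false, true);
  GX = Gb * W.t();
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Resample a single-channel 3-d volume under an affine "scale about the grid
// centre, then translate" map.  For output voxel v (0-based) the source
// coordinate is (v - c)/scale + c - shift with c = (dim - 1)/2.
// Trilinear interpolation (nearest = false) or nearest-neighbour; zero fill.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector x, NumericVector shift,
                             NumericVector scale, bool nearest) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("expected a 3-d array");
  const int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  const double c1 = (n1 - 1) / 2.0, c2 = (n2 - 1) / 2.0, c3 = (n3 - 1) / 2.0;
  NumericVector y(x.size());
  y.attr("dim") = dm;
  const double *px = x.begin();
  double *py = y.begin();

  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= n1 || j < 0 || j >= n2 || k < 0 || k >= n3) return 0.0;
    return px[i + static_cast<size_t>(n1) * (j + static_cast<size_t>(n2) * k)];
  };

  size_t t = 0;
  for (int k = 0; k < n3; ++k) {
    const double sk = (k - c3) / scale[2] + c3 - shift[2];
    for (int j = 0; j < n2; ++j) {
      const double sj = (j - c2) / scale[1] + c2 - shift[1];
      for (int i = 0; i < n1; ++i, ++t) {
        const double si = (i - c1) / scale[0] + c1 - shift[0];
        if (nearest) {
          const int ri = static_cast<int>(std::lround(si));
          const int rj = static_cast<int>(std::lround(sj));
          const int rk = static_cast<int>(std::lround(sk));
          py[t] = at(ri, rj, rk);
        } else {
          const int fi = static_cast<int>(std::floor(si));
          const int fj = static_cast<int>(std::floor(sj));
          const int fk = static_cast<int>(std::floor(sk));
          const double ai = si - fi, aj = sj - fj, ak = sk - fk;
          double v = 0.0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const double wgt = (di ? ai : 1 - ai) * (dj ? aj : 1 - aj) *
                                   (dk ? ak : 1 - ak);
                if (wgt > 0) v += wgt * at(fi + di, fj + dj, fk + dk);
              }
          py[t] = v;
        }
      }
    }
  }
  return y;
}
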
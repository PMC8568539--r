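// Low-level tensor kernels for the segmentation networks.
//
// Layout convention (matches R's column-major arrays):
//   feature maps  x : (H, W, C, N)
//   conv weights  w : (kh, kw, Cin, Cout)
// All convolutions are stride 1 with symmetric zero padding; pooling and
// transposed convolution are the fixed 2x2/stride-2 variants the U-shaped
// architecture uses.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector num4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector int4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline void get_dim4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Fill the im2col matrix (Hout*Wout x K) for one sample; column k of the
// matrix holds the input shifted by kernel offset (ki, kj) for channel ci,
// with k = ki + kh*(kj + kw*ci) matching a column-major reshape of w.
// This orientation keeps every inner copy contiguous in both source and
// destination.
static void im2col(const double* xs, int H, int W, int Cin,
                   int kh, int kw, int pad, arma::mat& cols) {
  const int Hout = H + 2 * pad - kh + 1;
  const int Wout = W + 2 * pad - kw + 1;
  cols.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = xs + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int k = ki + kh * (kj + kw * ci);
        double* colk = cols.colptr(k);
        for (int oj = 0; oj < Wout; ++oj) {
          const int ij = oj + kj - pad;
          if (ij < 0 || ij >= W) continue;
          const int oi_lo = std::max(0, pad - ki);
          const int oi_hi = std::min(Hout, H + pad - ki);
          const double* src = xc + (size_t)ij * H + (oi_lo + ki - pad);
          double* dst = colk + oi_lo + (size_t)Hout * oj;
          std::copy(src, src + (oi_hi - oi_lo), dst);
        }
      }
    }
  }
}

// Scatter-add a (Hout*Wout x K) column matrix back onto the input image
// (exact adjoint of im2col).
static void col2im(const arma::mat& cols, int H, int W, int Cin,
                   int kh, int kw, int pad, double* xs) {
  const int Hout = H + 2 * pad - kh + 1;
  const int Wout = W + 2 * pad - kw + 1;
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = xs + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int k = ki + kh * (kj + kw * ci);
        const double* colk = cols.colptr(k);
        for (int oj = 0; oj < Wout; ++oj) {
          const int ij = oj + kj - pad;
          if (ij < 0 || ij >= W) continue;
          const int oi_lo = std::max(0, pad - ki);
          const int oi_hi = std::min(Hout, H + pad - ki);
          double* dst = xc + (size_t)ij * H + (oi_lo + ki - pad);
          const double* src = colk + oi_lo + (size_t)Hout * oj;
          for (int oi = oi_lo; oi < oi_hi; ++oi) *dst++ += *src++;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int pad) {
  int dx[4], dw[4];
  get_dim4(x, dx); get_dim4(w, dw);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != Cin) stop("conv2d: channel mismatch");
  const int Hout = H + 2 * pad - kh + 1;
  const int Wout = W + 2 * pad - kw + 1;
  if (Hout < 1 || Wout < 1) stop("conv2d: kernel larger than padded input");
  const int K = kh * kw * Cin;

  NumericVector y = num4(Hout, Wout, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat cols((size_t)Hout * Wout, K);

  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * Cin;
    im2col(xs, H, W, Cin, kh, kw, pad, cols);
    arma::mat Ym(y.begin() + (size_t)n * Hout * Wout * Cout,
                 (size_t)Hout * Wout, Cout, false, true);
    Ym = cols * Wm;
    Ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy, int pad) {
  int dx_[4], dw_[4], dyd[4];
  get_dim4(x, dx_); get_dim4(w, dw_); get_dim4(dy, dyd);
  const int H = dx_[0], W = dx_[1], Cin = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], Cout = dw_[3];
  const int Hout = dyd[0], Wout = dyd[1];
  const int K = kh * kw * Cin;

  NumericVector dxv = num4(H, W, Cin, N);
  NumericVector dwv = num4(kh, kw, Cin, Cout);
  NumericVector dbv(Cout);

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWm(dwv.begin(), K, Cout, false, true);
  arma::rowvec dB(dbv.begin(), Cout, false, true);
  arma::mat cols((size_t)Hout * Wout, K);
  arma::mat dcols((size_t)Hout * Wout, K);

  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * Cin;
    arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)n * Hout * Wout * Cout,
                  (size_t)Hout * Wout, Cout, false, true);
    im2col(xs, H, W, Cin, kh, kw, pad, cols);
    dWm += cols.t() * dYm;
    dB += arma::sum(dYm, 0);
    dcols = dYm * Wm.t();
    col2im(dcols, H, W, Cin, kh, kw, pad,
           dxv.begin() + (size_t)n * H * W * Cin);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// 2x2 max pooling, stride 2; idx stores 0-based argmax offsets into the
// (H, W, C) sample block so the backward pass is an exact scatter.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  int d[4];
  get_dim4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = num4(Ho, Wo, C, N);
  IntegerVector idx = int4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    double* ys = y.begin() + (size_t)n * Ho * Wo * C;
    int* is = idx.begin() + (size_t)n * Ho * Wo * C;
    for (int c = 0; c < C; ++c) {
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const int ii = 2 * oi + di, jj = 2 * oj + dj;
              const int off = ii + H * (jj + W * c);
              if (xs[off] > best) { best = xs[off]; bi = off; }
            }
          }
          const int oo = oi + Ho * (oj + Wo * c);
          ys[oo] = best;
          is[oo] = bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx,
                           IntegerVector in_dim) {
  int d[4];
  get_dim4(dy, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = in_dim[0], W = in_dim[1];
  NumericVector dx = num4(H, W, C, N);
  const size_t blk_in = (size_t)H * W * C, blk_out = (size_t)Ho * Wo * C;
  for (int n = 0; n < N; ++n) {
    const double* ds = dy.begin() + n * blk_out;
    const int* is = idx.begin() + n * blk_out;
    double* xs = dx.begin() + n * blk_in;
    for (size_t k = 0; k < blk_out; ++k) xs[is[k]] += ds[k];
  }
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2: exact 2x upsampling.
// y[2i+di, 2j+dj, co] = b[co] + sum_ci x[i,j,ci] * w[di,dj,ci,co]
// [[Rcpp::export(name = ".upconv2_fwd")]]
NumericVector upconv2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int dx_[4], dw_[4];
  get_dim4(x, dx_); get_dim4(w, dw_);
  const int H = dx_[0], W = dx_[1], Cin = dx_[2], N = dx_[3];
  const int Cout = dw_[3];
  if (dw_[0] != 2 || dw_[1] != 2 || dw_[2] != Cin) stop("upconv2: bad weights");
  NumericVector y = num4(2 * H, 2 * W, Cout, N);
  // M: (4*Cout) x Cin with row index m + 4*co, m = di + 2*dj
  arma::mat M(4 * Cout, Cin);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int m = 0; m < 4; ++m)
        M(m + 4 * co, ci) = w[m + 4 * (ci + Cin * co)];

  arma::mat Y4(4 * Cout, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * Cin,
                 (size_t)H * W, Cin, false, true);
    Y4 = M * Xm.t();
    double* ys = y.begin() + (size_t)n * 4 * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          const size_t p = i + (size_t)H * j;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di)
              ys[(2 * i + di) + (size_t)2 * H * ((2 * j + dj) + (size_t)2 * W * co)] =
                bc + Y4(di + 2 * dj + 4 * co, p);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upconv2_bwd")]]
List upconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int dx_[4], dw_[4];
  get_dim4(x, dx_); get_dim4(w, dw_);
  const int H = dx_[0], W = dx_[1], Cin = dx_[2], N = dx_[3];
  const int Cout = dw_[3];
  NumericVector dxv = num4(H, W, Cin, N);
  NumericVector dwv = num4(2, 2, Cin, Cout);
  NumericVector dbv(Cout);

  arma::mat M(4 * Cout, Cin);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int m = 0; m < 4; ++m)
        M(m + 4 * co, ci) = w[m + 4 * (ci + Cin * co)];
  arma::mat dM(4 * Cout, Cin, arma::fill::zeros);
  arma::mat dY4(4 * Cout, (size_t)H * W);

  for (int n = 0; n < N; ++n) {
    const double* ds = dy.begin() + (size_t)n * 4 * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      double acc = 0.0;
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          const size_t p = i + (size_t)H * j;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const double g = ds[(2 * i + di) +
                (size_t)2 * H * ((2 * j + dj) + (size_t)2 * W * co)];
              dY4(di + 2 * dj + 4 * co, p) = g;
              acc += g;
            }
        }
      }
      dbv[co] += acc;
    }
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * Cin,
                 (size_t)H * W, Cin, false, true);
    dM += dY4 * Xm;
    arma::mat dXm(dxv.begin() + (size_t)n * H * W * Cin,
                  (size_t)H * W, Cin, false, true);
    dXm = dY4.t() * M;  // (HW x Cin)
  }
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int m = 0; m < 4; ++m)
        dwv[m + 4 * (ci + Cin * co)] = dM(m + 4 * co, ci);
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}
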
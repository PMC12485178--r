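// Convolution primitives for the encoder/decoder stacks.
//
// Layout conventions (column-major, matching R arrays):
//   feature maps  x : (H, W, C, N)
//   conv weights  w : (kh, kw, Cin, Cout)
//   deconv weights w: (kh, kw, Cout, Cin)
// im2col rows are ordered (ki fastest, then kj, then channel) so the natural
// memory view of the weight array is already the GEMM operand; no repacking.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather K x P patch matrix from one (H, W, C) slice.
// K = kh*kw*C, P = Ho*Wo; out-of-range positions are zero (implicit padding).
static void im2col_slice(const double* x, int H, int W, int C,
                         int kh, int kw, int stride, int pad,
                         int Ho, int Wo, arma::mat& cols) {
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        double* crow = cols.memptr() + r; // stride K between columns
        const int K = cols.n_rows;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            crow[(size_t)(ho + Ho * wo) * K] = xc[hi + H * wi];
          }
        }
      }
    }
  }
}

// Adjoint of im2col_slice: scatter-add cols back into the (H, W, C) slice.
static void col2im_slice(const arma::mat& cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad,
                         int Ho, int Wo, double* x) {
  const int K = cols.n_rows;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        const double* crow = cols.memptr() + r;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            xc[hi + H * wi] += crow[(size_t)(ho + Ho * wo) * K];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w,
                            NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const int K = kh * kw * Cin, P = Ho * Wo;
  NumericVector y((R_xlen_t)(Ho) * (R_xlen_t)(Wo) * (R_xlen_t)(Cout) * (R_xlen_t)(N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat cols(K, P);
  arma::rowvec b(const_cast<double*>(bias.begin()), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    im2col_slice(x.begin() + (size_t)n * H * W * C, H, W, C,
                 kh, kw, stride, pad, Ho, Wo, cols);
    arma::mat Yt(y.begin() + (size_t)n * P * Cout, P, Cout, false, true);
    Yt = cols.t() * Wm;
    Yt.each_row() += b;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const int K = kh * kw * Cin, P = Ho * Wo;
  NumericVector dx((R_xlen_t)(H) * (R_xlen_t)(W) * (R_xlen_t)(C) * (R_xlen_t)(N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)(kh) * (R_xlen_t)(kw) * (R_xlen_t)(Cin) * (R_xlen_t)(Cout));
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::rowvec dB(db.begin(), Cout, false, true);
  arma::mat cols(K, P), dcols(K, P);
  for (int n = 0; n < N; ++n) {
    im2col_slice(x.begin() + (size_t)n * H * W * C, H, W, C,
                 kh, kw, stride, pad, Ho, Wo, cols);
    arma::mat dYt(const_cast<double*>(dy.begin()) + (size_t)n * P * Cout,
                  P, Cout, false, true);
    dWm += cols * dYt;
    dB += arma::sum(dYt, 0);
    dcols = Wm * dYt.t();
    col2im_slice(dcols, H, W, C, kh, kw, stride, pad, Ho, Wo,
                 dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed (fractionally strided) convolution.
// Output side: (in - 1)*stride - 2*pad + k + output_padding.
// [[Rcpp::export]]
NumericVector convt2d_fw_cpp(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, int pad,
                             int outpad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int Hin = xd[0], Win = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[2], Cin = wd[3];
  if (Cin != C) stop("convt2d: channel mismatch");
  const int Ho = (Hin - 1) * stride - 2 * pad + kh + outpad;
  const int Wo = (Win - 1) * stride - 2 * pad + kw + outpad;
  const int K = kh * kw * Cout, Pin = Hin * Win;
  NumericVector y((R_xlen_t)(Ho) * (R_xlen_t)(Wo) * (R_xlen_t)(Cout) * (R_xlen_t)(N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cin, false, true);
  arma::mat cols(K, Pin);
  for (int n = 0; n < N; ++n) {
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)n * Pin * Cin,
                 Pin, Cin, false, true);
    cols = Wm * Xm.t();
    // scatter: roles of image/grid are reversed relative to conv
    col2im_slice(cols, Ho, Wo, Cout, kh, kw, stride, pad, Hin, Win,
                 y.begin() + (size_t)n * Ho * Wo * Cout);
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      double* yc = y.begin() + (size_t)(c + (size_t)n * Cout) * Ho * Wo;
      const double b = bias[c];
      for (int p = 0; p < Ho * Wo; ++p) yc[p] += b;
    }
  return y;
}

// [[Rcpp::export]]
List convt2d_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int outpad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int Hin = xd[0], Win = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[2], Cin = wd[3];
  const int Ho = (Hin - 1) * stride - 2 * pad + kh + outpad;
  const int Wo = (Win - 1) * stride - 2 * pad + kw + outpad;
  const int K = kh * kw * Cout, Pin = Hin * Win;
  NumericVector dx((R_xlen_t)(Hin) * (R_xlen_t)(Win) * (R_xlen_t)(C) * (R_xlen_t)(N));
  dx.attr("dim") = IntegerVector::create(Hin, Win, C, N);
  NumericVector dw((R_xlen_t)(kh) * (R_xlen_t)(kw) * (R_xlen_t)(Cout) * (R_xlen_t)(Cin));
  dw.attr("dim") = IntegerVector::create(kh, kw, Cout, Cin);
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cin, false, true);
  arma::mat dWm(dw.begin(), K, Cin, false, true);
  arma::mat dcols(K, Pin);
  for (int n = 0; n < N; ++n) {
    im2col_slice(dy.begin() + (size_t)n * Ho * Wo * Cout, Ho, Wo, Cout,
                 kh, kw, stride, pad, Hin, Win, dcols);
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)n * Pin * Cin,
                 Pin, Cin, false, true);
    arma::mat dXm(dx.begin() + (size_t)n * Pin * Cin, Pin, Cin, false, true);
    dXm = dcols.t() * Wm;
    dWm += dcols * Xm;
    for (int c = 0; c < Cout; ++c) {
      const double* dyc = dy.begin() + (size_t)(c + (size_t)n * Cout) * Ho * Wo;
      double s = 0.0;
      for (int p = 0; p < Ho * Wo; ++p) s += dyc[p];
      db[c] += s;
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2d_fw_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y((R_xlen_t)(Ho) * (R_xlen_t)(Wo) * (R_xlen_t)(C) * (R_xlen_t)(N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector amax((R_xlen_t)(Ho) * (R_xlen_t)(Wo) * (R_xlen_t)(C) * (R_xlen_t)(N));
  amax.attr("dim") = IntegerVector::create(Ho, Wo, C, N); // 0-based index into full x
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)(c + (size_t)n * C) * H * W;
      const double* xc = x.begin() + off;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              const double v = xc[hi + H * wi];
              if (v > best) { best = v; bi = hi + H * wi; }
            }
          }
          const size_t oidx = (size_t)(ho + Ho * (wo + Wo * (c + C * (size_t)n)));
          y[oidx] = best;
          amax[oidx] = (int)(bi + off);
        }
    }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool2d_bw_cpp(IntegerVector argmax, NumericVector dy,
                               IntegerVector xdim) {
  NumericVector dx((R_xlen_t)(xdim[0]) * (R_xlen_t)(xdim[1]) * (R_xlen_t)(xdim[2]) * (R_xlen_t)(xdim[3]));
  dx.attr("dim") = IntegerVector::create(xdim[0], xdim[1], xdim[2], xdim[3]);
  const int n = dy.size();
  for (int i = 0; i < n; ++i) dx[argmax[i]] += dy[i];
  return dx;
}

// column-wise max and (0-based) argmax of a dense matrix
// [[Rcpp::export]]
List colmax_cpp(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector mx(nc);
  IntegerVector ix(nc);
  for (int j = 0; j < nc; ++j) {
    const double* col = &m(0, j);
    double best = col[0];
    int bi = 0;
    for (int i = 1; i < nr; ++i)
      if (col[i] > best) { best = col[i]; bi = i; }
    mx[j] = best;
    ix[j] = bi;
  }
  return List::create(_["max"] = mx, _["idx"] = ix);
}

// [[Rcpp::export]]
NumericVector relu_fw_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// gradient of relu given the forward output
// [[Rcpp::export]]
NumericVector relu_bw_cpp(NumericVector g, NumericVector y) {
  NumericVector dx(g.size());
  dx.attr("dim") = g.attr("dim");
  const double* gp = g.begin();
  const double* yp = y.begin();
  double* dp = dx.begin();
  const R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) dp[i] = yp[i] > 0 ? gp[i] : 0.0;
  return dx;
}

// Batch-norm core: per-channel statistics over (H, W, N) in one pass.
// [[Rcpp::export]]
List bn_fw_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector mu_in, NumericVector var_in, bool training,
               double eps) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector mu(C), var(C);
  if (training) {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const double* xc = x.begin() + (size_t)(c + (size_t)n * C) * HW;
        double s = 0;
        for (int i = 0; i < HW; ++i) s += xc[i];
        mu[c] += s;
      }
    for (int c = 0; c < C; ++c) mu[c] /= (double)HW * N;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const double* xc = x.begin() + (size_t)(c + (size_t)n * C) * HW;
        double s = 0, m = mu[c];
        for (int i = 0; i < HW; ++i) { const double d = xc[i] - m; s += d * d; }
        var[c] += s;
      }
    for (int c = 0; c < C; ++c) var[c] /= (double)HW * N;
  } else {
    mu = clone(mu_in);
    var = clone(var_in);
  }
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  NumericVector inv(C);
  for (int c = 0; c < C; ++c) inv[c] = 1.0 / std::sqrt(var[c] + eps);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(c + (size_t)n * C) * HW;
      double* yc = y.begin() + (size_t)(c + (size_t)n * C) * HW;
      const double a = gamma[c] * inv[c];
      const double b = beta[c] - a * mu[c];
      for (int i = 0; i < HW; ++i) yc[i] = a * xc[i] + b;
    }
  return List::create(_["y"] = y, _["mu"] = mu, _["var"] = var,
                      _["inv"] = inv);
}

// [[Rcpp::export]]
List bn_bw_cpp(NumericVector x, NumericVector g, NumericVector mu,
               NumericVector inv, NumericVector gamma, bool training) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const double M = (double)HW * N;
  NumericVector dgamma(C), dbeta(C), t1(C), t2(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(c + (size_t)n * C) * HW;
      const double* gc = g.begin() + (size_t)(c + (size_t)n * C) * HW;
      double sg = 0, sgx = 0;
      const double m = mu[c], iv = inv[c];
      for (int i = 0; i < HW; ++i) {
        sg += gc[i];
        sgx += gc[i] * (xc[i] - m) * iv;
      }
      dbeta[c] += sg;
      dgamma[c] += sgx;
    }
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  for (int c = 0; c < C; ++c) { t1[c] = dbeta[c] / M; t2[c] = dgamma[c] / M; }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(c + (size_t)n * C) * HW;
      const double* gc = g.begin() + (size_t)(c + (size_t)n * C) * HW;
      double* dc = dx.begin() + (size_t)(c + (size_t)n * C) * HW;
      const double ga = gamma[c], iv = inv[c], m = mu[c];
      if (training) {
        for (int i = 0; i < HW; ++i)
          dc[i] = ga * iv * (gc[i] - t1[c] - (xc[i] - m) * iv * t2[c]);
      } else {
        for (int i = 0; i < HW; ++i) dc[i] = ga * iv * gc[i];
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
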
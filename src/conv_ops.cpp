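// Convolution and pooling kernels for the autodiff engine.
//
// Tensor layout everywhere: column-major R arrays with dim (H, W, C, N),
// i.e. element (h, w, c, n) sits at h + H*(w + W*(c + C*n)).
// Convolution weights: dim (k, k, Cin, Cout). Convolutions are computed by
// im2col + GEMM; the im2col row index is kh + k*kw + k*k*cin so that the
// reshaped weight matrix (k*k*Cin x Cout) lines up with the column-major
// weight array.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill `cols` (k*k*Cin x Ho*Wo) from one sample of x. Zero padding.
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& cols) {
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            cols(r, ho + (size_t)Ho * wo) = xc[hi + (size_t)H * wi];
          }
        }
      }
    }
  }
}

// Scatter-add the columns back into one sample of gx (inverse of im2col).
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            gc[hi + (size_t)H * wi] += cols(r, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");

  NumericVector out(Ho * (size_t)Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  const arma::mat wmat(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::mat cols(k * k * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, cols);
    arma::mat o(out.begin() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo, Cout, false, true);
    o = cols.t() * wmat;
    for (int co = 0; co < Cout; ++co) o.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                         int stride, int pad, bool need_gx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector(x.size());
    gx.attr("dim") = xd;
  }

  const arma::mat wmat(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::mat gwm(gw.begin(), k * k * Cin, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);
  arma::mat cols(k * k * Cin, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const arma::mat go(const_cast<double*>(gout.begin()) + (size_t)n * Ho * Wo * Cout,
                       (size_t)Ho * Wo, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, cols);
    gwm += cols * go;
    gbv += arma::sum(go, 0).t();
    if (need_gx) {
      arma::mat gcols = wmat * go.t();
      col2im(gcols, H, W, C, k, stride, pad, Ho, Wo,
             gx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns the pooled map and the argmax code
// (0..3, = dh + 2*dw) needed by the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(out.size());
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  for (int q = 0; q < C * N; ++q) {
    const double* xp = x.begin() + (size_t)q * H * W;
    double* op = out.begin() + (size_t)q * Ho * Wo;
    int* ap = arg.begin() + (size_t)q * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -1e300;
        int code = 0;
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            const double v = xp[(2 * ho + dh) + (size_t)H * (2 * wo + dw)];
            if (v > best) { best = v; code = dh + 2 * dw; }
          }
        }
        op[ho + (size_t)Ho * wo] = best;
        ap[ho + (size_t)Ho * wo] = code;
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector gout, IntegerVector arg,
                                    int H, int W) {
  IntegerVector od = gout.attr("dim");
  const int Ho = od[0], Wo = od[1], C = od[2], N = od[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double* gp = gout.begin() + (size_t)q * Ho * Wo;
    const int* ap = arg.begin() + (size_t)q * Ho * Wo;
    double* xp = gx.begin() + (size_t)q * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int code = ap[ho + (size_t)Ho * wo];
        const int dh = code % 2, dw = code / 2;
        xp[(2 * ho + dh) + (size_t)H * (2 * wo + dw)] += gp[ho + (size_t)Ho * wo];
      }
    }
  }
  return gx;
}
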
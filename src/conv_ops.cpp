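// 2-D convolution kernels for the autodiff engine.
// Tensor layout follows R arrays: x[H, W, C] column-major, weights
// w[kh, kw, Cin, Cout]. Convolution is cross-correlation (the deep-learning
// convention) with implicit zero padding.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw,
                        int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat K(kh * kw * C, (arma::uword)Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const arma::uword col = (arma::uword)ho + (arma::uword)Ho * wo;
        const int h0 = ho * stride - pad, w0 = wo * stride - pad;
        for (int dw = 0; dw < kw; ++dw) {
          const int wi = w0 + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int hi = h0 + dh;
            if (hi < 0 || hi >= H) continue;
            K(dh + kh * (dw + kw * c), col) = xc(hi, wi);
          }
        }
      }
    }
  }
  return K;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x_, NumericVector w_,
                             NumericVector b_, int stride, int pad) {
  IntegerVector xd = x_.attr("dim"), wd = w_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::cube x(x_.begin(), H, W, C, false);
  arma::mat Wmat(w_.begin(), (arma::uword)kh * kw * Cin, Cout, false);
  arma::mat K = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat Y = K.t() * Wmat;               // (Ho*Wo) x Cout
  for (int co = 0; co < Cout; ++co) Y.col(co) += b_[co];
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x_, NumericVector w_, NumericVector gy_,
                    int stride, int pad) {
  IntegerVector xd = x_.attr("dim"), wd = w_.attr("dim"), gd = gy_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  arma::cube x(x_.begin(), H, W, C, false);
  arma::mat Wmat(w_.begin(), (arma::uword)kh * kw * Cin, Cout, false);
  arma::mat GY(gy_.begin(), (arma::uword)Ho * Wo, Cout, false);

  arma::mat K = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat gW = K * GY;                    // (kh*kw*Cin) x Cout
  arma::rowvec gb = arma::sum(GY, 0);
  arma::mat gK = Wmat * GY.t();             // (kh*kw*Cin) x (Ho*Wo)

  arma::cube gx(H, W, C, arma::fill::zeros);  // col2im scatter-add
  for (int c = 0; c < C; ++c) {
    arma::mat& gxc = gx.slice(c);
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const arma::uword col = (arma::uword)ho + (arma::uword)Ho * wo;
        const int h0 = ho * stride - pad, w0 = wo * stride - pad;
        for (int dw = 0; dw < kw; ++dw) {
          const int wi = w0 + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int hi = h0 + dh;
            if (hi < 0 || hi >= H) continue;
            gxc(hi, wi) += gK(dh + kh * (dw + kw * c), col);
          }
        }
      }
    }
  }

  NumericVector gx_(gx.begin(), gx.end());
  gx_.attr("dim") = IntegerVector::create(H, W, C);
  NumericVector gW_(gW.begin(), gW.end());
  gW_.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector gb_(gb.begin(), gb.end());
  return List::create(_["gx"] = gx_, _["gw"] = gW_, _["gb"] = gb_);
}
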
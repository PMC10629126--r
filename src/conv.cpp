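// Batched 2-D convolution kernels for the encoder-decoder engine.
// Tensors arrive as column-major R arrays laid out (H, W, B, C); the
// convolution is 'same' with zero padding. The im2col matrix is built
// once per call and multiplied against the reshaped weights with BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather the shifted-slice (im2col) matrix: rows ordered (H, W, B),
// columns ordered (kr, kc, ci) to match matrix(W, k*k*Cin, Cout).
static arma::mat im2col(const double* xp, int H, int W, int B, int Cin,
                        int k) {
  int p = (k - 1) / 2;
  arma::uword HWB = (arma::uword)H * W * B;
  arma::mat cols(HWB, (arma::uword)k * k * Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        arma::uword col = (arma::uword)ci * k * k + (arma::uword)kc * k + kr;
        double* dst = cols.colptr(col);
        int dr = kr - p, dc = kc - p;
        for (int b = 0; b < B; ++b) {
          const double* xb = xp + ((arma::uword)ci * B + b) * H * W;
          double* dslice = dst + (arma::uword)b * H * W;
          for (int c = 0; c < W; ++c) {
            double* dcol = dslice + (arma::uword)c * H;
            int sc = c + dc;
            if (sc < 0 || sc >= W) {
              std::fill(dcol, dcol + H, 0.0);
              continue;
            }
            const double* scol = xb + (arma::uword)sc * H;
            int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
            for (int r = 0; r < r0; ++r) dcol[r] = 0.0;
            for (int r = r0; r < r1; ++r) dcol[r] = scol[r + dr];
            for (int r = r1; r < H; ++r) dcol[r] = 0.0;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, IntegerVector xdim,
                           NumericVector w, IntegerVector wdim,
                           NumericVector bias) {
  int H = xdim[0], W = xdim[1], B = xdim[2], Cin = xdim[3];
  int k = wdim[0], Cout = wdim[3];
  arma::mat cols = im2col(x.begin(), H, W, B, Cin, k);
  arma::mat Wm(w.begin(), (arma::uword)k * k * Cin, Cout, false);
  arma::mat out = cols * Wm;
  for (int co = 0; co < Cout; ++co) out.col(co) += bias[co];
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H, W, B, Cout);
  return res;
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector dout, NumericVector x, IntegerVector xdim,
                  NumericVector w, IntegerVector wdim) {
  int H = xdim[0], W = xdim[1], B = xdim[2], Cin = xdim[3];
  int k = wdim[0], Cout = wdim[3];
  int p = (k - 1) / 2;
  arma::uword HWB = (arma::uword)H * W * B;
  arma::mat cols = im2col(x.begin(), H, W, B, Cin, k);
  arma::mat dm(dout.begin(), HWB, Cout, false);
  arma::mat Wm(w.begin(), (arma::uword)k * k * Cin, Cout, false);
  arma::mat dWm = cols.t() * dm;
  arma::rowvec db = arma::sum(dm, 0);
  arma::mat dcols = dm * Wm.t();
  NumericVector dx(x.size());
  double* dxp = dx.begin();
  // adjoint of the gather: scatter-add each im2col column back
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        arma::uword col = (arma::uword)ci * k * k + (arma::uword)kc * k + kr;
        const double* src = dcols.colptr(col);
        int dr = kr - p, dc = kc - p;
        for (int b = 0; b < B; ++b) {
          double* xb = dxp + ((arma::uword)ci * B + b) * H * W;
          const double* sslice = src + (arma::uword)b * H * W;
          for (int c = 0; c < W; ++c) {
            int sc = c + dc;
            if (sc < 0 || sc >= W) continue;
            double* dcol = xb + (arma::uword)sc * H;
            const double* scol = sslice + (arma::uword)c * H;
            int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
            for (int r = r0; r < r1; ++r) dcol[r + dr] += scol[r];
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  NumericVector dW(dWm.begin(), dWm.end());
  dW.attr("dim") = wdim;
  return List::create(Named("dx") = dx, Named("dW") = dW,
                      Named("db") = NumericVector(db.begin(), db.end()));
}
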
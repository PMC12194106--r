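// Dense 2-D convolution kernels (stride 1, odd kernel, "same" padding equal
// to dilation*(k-1)/2). Tensors are column-major (C, H, W, B) arrays; each
// kernel tap contributes one GEMM on a shifted view of the padded input.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void pad_input(const double* x, arma::mat& xp,
                      int C, int H, int W, int B, int p) {
  // xp is C x (Hp*Wp*B) zeroed; copy column blocks of length C*H
  const int Hp = H + 2 * p;
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < W; ++w) {
      const double* src = x + (size_t)C * H * (w + (size_t)W * b);
      double* dst = xp.memptr() +
        (size_t)C * (p + (size_t)Hp * (w + p + (size_t)(W + 2 * p) * b));
      std::memcpy(dst, src, sizeof(double) * (size_t)C * H);
    }
  }
}

// gather the shifted view for tap offset (oi, oj) into buf (C x H*W*B)
static void gather_tap(const arma::mat& xp, arma::mat& buf,
                       int C, int H, int W, int B, int p, int oi, int oj) {
  const int Hp = H + 2 * p;
  const int Wp = W + 2 * p;
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < W; ++w) {
      const double* src = xp.memptr() +
        (size_t)C * (oi + (size_t)Hp * (w + oj + (size_t)Wp * b));
      double* dst = buf.memptr() + (size_t)C * H * (w + (size_t)W * b);
      std::memcpy(dst, src, sizeof(double) * (size_t)C * H);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, int dilation) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], B = xd[3];
  const int cout = wd[0], cin = wd[1], k = wd[2];
  const int p = dilation * (k - 1) / 2;
  const size_t N = (size_t)H * W * B;

  arma::mat xp(C, (size_t)(H + 2 * p) * (W + 2 * p) * B, arma::fill::zeros);
  pad_input(x.begin(), xp, C, H, W, B, p);
  arma::mat buf(cin, N);
  arma::mat y(cout, N, arma::fill::zeros);
  arma::mat wt(cout, cin);
  for (int a = 0; a < k; ++a) {
    for (int b = 0; b < k; ++b) {
      for (int j = 0; j < cin; ++j)
        for (int i = 0; i < cout; ++i)
          wt(i, j) = w[i + (size_t)cout * (j + (size_t)cin * (a + (size_t)k * b))];
      gather_tap(xp, buf, cin, H, W, B, p, a * dilation, b * dilation);
      y += wt * buf;
    }
  }
  NumericVector out(y.memptr(), y.memptr() + y.n_elem);
  out.attr("dim") = IntegerVector::create(cout, H, W, B);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int dilation) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], B = xd[3];
  const int cout = wd[0], cin = wd[1], k = wd[2];
  const int p = dilation * (k - 1) / 2;
  const size_t N = (size_t)H * W * B;

  arma::mat xp(C, (size_t)(H + 2 * p) * (W + 2 * p) * B, arma::fill::zeros);
  pad_input(x.begin(), xp, C, H, W, B, p);
  arma::mat dyp(cout, (size_t)(H + 2 * p) * (W + 2 * p) * B, arma::fill::zeros);
  pad_input(dy.begin(), dyp, cout, H, W, B, p);
  const arma::mat dym(const_cast<double*>(dy.begin()), cout, N, false, true);

  arma::mat bufx(cin, N), bufd(cout, N);
  arma::mat dx(cin, N, arma::fill::zeros);
  NumericVector dwv((size_t)cout * cin * k * k);
  arma::mat wt(cout, cin);
  for (int a = 0; a < k; ++a) {
    for (int b = 0; b < k; ++b) {
      const int oi = a * dilation, oj = b * dilation;
      gather_tap(xp, bufx, cin, H, W, B, p, oi, oj);
      arma::mat dw_tap = dym * bufx.t();  // cout x cin
      for (int j = 0; j < cin; ++j)
        for (int i = 0; i < cout; ++i)
          dwv[i + (size_t)cout * (j + (size_t)cin * (a + (size_t)k * b))] = dw_tap(i, j);
      for (int j = 0; j < cin; ++j)
        for (int i = 0; i < cout; ++i)
          wt(i, j) = w[i + (size_t)cout * (j + (size_t)cin * (a + (size_t)k * b))];
      // input gradient: flipped-kernel convolution of dy
      gather_tap(dyp, bufd, cout, H, W, B, p, 2 * p - oi, 2 * p - oj);
      dx += wt.t() * bufd;
    }
  }
  NumericVector dxv(dx.memptr(), dx.memptr() + dx.n_elem);
  dxv.attr("dim") = IntegerVector::create(cin, H, W, B);
  dwv.attr("dim") = IntegerVector::create(cout, cin, k, k);
  return List::create(Named("dx") = dxv, Named("dw") = dwv);
}
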
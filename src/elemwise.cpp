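// Fused elementwise kernels for the hot training path: batch-norm
// statistics/apply/backward, per-channel gating, ReLU.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x, int C) {
  const size_t n = x.size();
  const size_t N = n / C;
  NumericVector mu(C), var(C);
  const double* p = x.begin();
  for (size_t j = 0; j < N; ++j) {
    const double* col = p + (size_t)C * j;
    for (int c = 0; c < C; ++c) {
      mu[c] += col[c];
      var[c] += col[c] * col[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    mu[c] /= N;
    var[c] = var[c] / N - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(Named("mean") = mu, Named("var") = var);
}

// y = gamma * (x - mu) * inv + beta, xhat kept for backward
// [[Rcpp::export]]
List cpp_bn_apply(NumericVector x, NumericVector mu, NumericVector inv,
                  NumericVector gamma, NumericVector beta, bool keep_xhat) {
  const int C = mu.size();
  const size_t n = x.size();
  const size_t N = n / C;
  NumericVector y(n);
  NumericVector xhat(keep_xhat ? n : 0);
  const double* px = x.begin();
  double* py = y.begin();
  double* ph = keep_xhat ? xhat.begin() : nullptr;
  for (size_t j = 0; j < N; ++j) {
    const size_t off = (size_t)C * j;
    for (int c = 0; c < C; ++c) {
      const double h = (px[off + c] - mu[c]) * inv[c];
      if (keep_xhat) ph[off + c] = h;
      py[off + c] = gamma[c] * h + beta[c];
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(Named("y") = y, Named("xhat") = xhat);
}

// training-mode backward: returns dx, dgamma, dbeta
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector gamma,
                NumericVector inv) {
  const int C = gamma.size();
  const size_t n = dy.size();
  const size_t N = n / C;
  NumericVector dgamma(C), dbeta(C), dx(n);
  const double* pd = dy.begin();
  const double* ph = xhat.begin();
  for (size_t j = 0; j < N; ++j) {
    const size_t off = (size_t)C * j;
    for (int c = 0; c < C; ++c) {
      dgamma[c] += pd[off + c] * ph[off + c];
      dbeta[c] += pd[off + c];
    }
  }
  std::vector<double> m1(C), m2(C);
  for (int c = 0; c < C; ++c) {
    m1[c] = dbeta[c] / N;          // mean(dy)
    m2[c] = dgamma[c] / N;         // mean(dy * xhat)
  }
  double* px = dx.begin();
  for (size_t j = 0; j < N; ++j) {
    const size_t off = (size_t)C * j;
    for (int c = 0; c < C; ++c) {
      px[off + c] = gamma[c] * inv[c] *
        (pd[off + c] - m1[c] - ph[off + c] * m2[c]);
    }
  }
  dx.attr("dim") = dy.attr("dim");
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// eval-mode backward: dx = dy * gamma * inv (per channel)
// [[Rcpp::export]]
NumericVector cpp_bn_bwd_eval(NumericVector dy, NumericVector gamma,
                              NumericVector inv) {
  const int C = gamma.size();
  const size_t n = dy.size();
  const size_t N = n / C;
  NumericVector dx(n);
  const double* pd = dy.begin();
  double* px = dx.begin();
  for (size_t j = 0; j < N; ++j) {
    const size_t off = (size_t)C * j;
    for (int c = 0; c < C; ++c) px[off + c] = pd[off + c] * gamma[c] * inv[c];
  }
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// per-channel, per-sample gate: y[c,s,b] = x[c,s,b] * g[c,b]
// [[Rcpp::export]]
NumericVector cpp_chmul(NumericVector x, NumericMatrix g, int HW) {
  const int C = g.nrow();
  const int B = g.ncol();
  NumericVector y(x.size());
  const double* px = x.begin();
  double* py = y.begin();
  for (int b = 0; b < B; ++b) {
    for (int s = 0; s < HW; ++s) {
      const size_t off = (size_t)C * (s + (size_t)HW * b);
      for (int c = 0; c < C; ++c) py[off + c] = px[off + c] * g(c, b);
    }
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// returns dg[c,b] = sum_s dy*x ; dx = dy * g
// [[Rcpp::export]]
List cpp_chmul_bwd(NumericVector dy, NumericVector x, NumericMatrix g, int HW) {
  const int C = g.nrow();
  const int B = g.ncol();
  NumericVector dx(dy.size());
  NumericMatrix dg(C, B);
  const double* pd = dy.begin();
  const double* px = x.begin();
  double* pdx = dx.begin();
  for (int b = 0; b < B; ++b) {
    for (int s = 0; s < HW; ++s) {
      const size_t off = (size_t)C * (s + (size_t)HW * b);
      for (int c = 0; c < C; ++c) {
        pdx[off + c] = pd[off + c] * g(c, b);
        dg(c, b) += pd[off + c] * px[off + c];
      }
    }
  }
  dx.attr("dim") = dy.attr("dim");
  return List::create(Named("dx") = dx, Named("dg") = dg);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* px = x.begin();
  double* py = y.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) py[i] = px[i] > 0 ? px[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector x) {
  NumericVector dx(dy.size());
  const double* pd = dy.begin();
  const double* px = x.begin();
  double* pdx = dx.begin();
  const size_t n = dy.size();
  for (size_t i = 0; i < n; ++i) pdx[i] = px[i] > 0 ? pd[i] : 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
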
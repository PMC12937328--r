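// Fused numeric kernels for the training hot path. Feature matrices are
// channel-major [C x M]; batch-norm statistics run along the M (element)
// dimension. Only operations that dominate the interpreted profile live
// here; everything with BLAS-level arithmetic stays in R.

#include <Rcpp.h>
using namespace Rcpp;

// Batch-norm training forward with population variance.
// Returns y, xhat, inv (1/sqrt(v+eps)), mu and v (for running updates).
// [[Rcpp::export]]
List bn_train_fwd_cpp(const NumericMatrix& x, const NumericVector& g,
                      const NumericVector& b, double eps) {
  const int C = x.nrow(), M = x.ncol();
  NumericVector mu(C), v(C), inv(C);
  const double* xp = x.begin();
  for (int j = 0; j < M; ++j) {
    const double* col = xp + (size_t)j * C;
    for (int i = 0; i < C; ++i) mu[i] += col[i];
  }
  for (int i = 0; i < C; ++i) mu[i] /= M;
  for (int j = 0; j < M; ++j) {
    const double* col = xp + (size_t)j * C;
    for (int i = 0; i < C; ++i) {
      const double d = col[i] - mu[i];
      v[i] += d * d;
    }
  }
  for (int i = 0; i < C; ++i) {
    v[i] /= M;
    inv[i] = 1.0 / std::sqrt(v[i] + eps);
  }
  NumericMatrix xhat(C, M), y(C, M);
  double* hp = xhat.begin();
  double* yp = y.begin();
  for (int j = 0; j < M; ++j) {
    const double* col = xp + (size_t)j * C;
    double* hcol = hp + (size_t)j * C;
    double* ycol = yp + (size_t)j * C;
    for (int i = 0; i < C; ++i) {
      const double h = (col[i] - mu[i]) * inv[i];
      hcol[i] = h;
      ycol[i] = g[i] * h + b[i];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv,
                      _["mu"] = mu, _["v"] = v);
}

// Batch-norm eval forward using running statistics.
// [[Rcpp::export]]
NumericMatrix bn_eval_fwd_cpp(const NumericMatrix& x, const NumericVector& g,
                              const NumericVector& b, const NumericVector& rm,
                              const NumericVector& rv, double eps) {
  const int C = x.nrow(), M = x.ncol();
  NumericVector a(C), o(C);
  for (int i = 0; i < C; ++i) {
    const double inv = 1.0 / std::sqrt(rv[i] + eps);
    a[i] = g[i] * inv;
    o[i] = b[i] - g[i] * rm[i] * inv;
  }
  NumericMatrix y(C, M);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int j = 0; j < M; ++j) {
    const double* col = xp + (size_t)j * C;
    double* ycol = yp + (size_t)j * C;
    for (int i = 0; i < C; ++i) ycol[i] = a[i] * col[i] + o[i];
  }
  return y;
}

// Batch-norm training backward (population-variance convention):
// dx = g*inv/M * (M*dy - sum(dy) - xhat * sum(dy*xhat)).
// [[Rcpp::export]]
List bn_train_bwd_cpp(const NumericMatrix& dy, const NumericMatrix& xhat,
                      const NumericVector& inv, const NumericVector& g) {
  const int C = dy.nrow(), M = dy.ncol();
  NumericVector sdy(C), sdyh(C);
  const double* dp = dy.begin();
  const double* hp = xhat.begin();
  for (int j = 0; j < M; ++j) {
    const double* dcol = dp + (size_t)j * C;
    const double* hcol = hp + (size_t)j * C;
    for (int i = 0; i < C; ++i) {
      sdy[i] += dcol[i];
      sdyh[i] += dcol[i] * hcol[i];
    }
  }
  NumericMatrix dx(C, M);
  double* op = dx.begin();
  NumericVector s(C);
  for (int i = 0; i < C; ++i) s[i] = g[i] * inv[i] / M;
  for (int j = 0; j < M; ++j) {
    const double* dcol = dp + (size_t)j * C;
    const double* hcol = hp + (size_t)j * C;
    double* ocol = op + (size_t)j * C;
    for (int i = 0; i < C; ++i)
      ocol[i] = s[i] * (M * dcol[i] - sdy[i] - hcol[i] * sdyh[i]);
  }
  return List::create(_["dx"] = dx, _["dg"] = sdyh, _["db"] = sdy);
}

// Channel-wise max over contiguous neighbor blocks of width K.
// [[Rcpp::export]]
List maxpool_fwd_cpp(const NumericMatrix& x, int K) {
  const int C = x.nrow();
  const int M = x.ncol() / K;
  NumericMatrix y(C, M);
  IntegerMatrix argm(C, M);
  const double* xp = x.begin();
  for (int m = 0; m < M; ++m) {
    const double* block = xp + (size_t)m * K * C;
    double* ycol = y.begin() + (size_t)m * C;
    int* acol = argm.begin() + (size_t)m * C;
    for (int i = 0; i < C; ++i) { ycol[i] = block[i]; acol[i] = 1; }
    for (int t = 1; t < K; ++t) {
      const double* col = block + (size_t)t * C;
      for (int i = 0; i < C; ++i) {
        if (col[i] > ycol[i]) { ycol[i] = col[i]; acol[i] = t + 1; }
      }
    }
  }
  return List::create(_["y"] = y, _["argm"] = argm);
}

// Scatter-add columns of dG into an all-zero [C x N] matrix at idx (1-based).
// [[Rcpp::export]]
NumericMatrix scatter_add_cols_cpp(const NumericMatrix& dG,
                                   const IntegerVector& idx, int N) {
  const int C = dG.nrow(), L = dG.ncol();
  NumericMatrix out(C, N);
  const double* gp = dG.begin();
  double* op = out.begin();
  for (int j = 0; j < L; ++j) {
    const double* gcol = gp + (size_t)j * C;
    double* ocol = op + (size_t)(idx[j] - 1) * C;
    for (int i = 0; i < C; ++i) ocol[i] += gcol[i];
  }
  return out;
}

// ReLU forward returning the output and the positive mask in one pass.
// [[Rcpp::export]]
List relu_fwd_cpp(const NumericMatrix& x) {
  const int C = x.nrow(), M = x.ncol();
  NumericMatrix y(C, M);
  LogicalMatrix mask(C, M);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* mp = mask.begin();
  const size_t n = (size_t)C * M;
  for (size_t i = 0; i < n; ++i) {
    const bool pos = xp[i] > 0;
    mp[i] = pos;
    yp[i] = pos ? xp[i] : 0.0;
  }
  return List::create(_["y"] = y, _["mask"] = mask);
}
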
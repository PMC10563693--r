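// im2col/GEMM convolution primitives for the small residual network.
// Arrays use R's column-major layout: images (H, W, C, N), kernels
// (k, k, Cin, Cout). All heavy lifting is a matrix product, so BLAS does
// the work; no RNG lives here (initialization and shuffling stay in R).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col(const double* x, int H, int W, int C, int k, int stride,
                   int pad, mat& col, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int row = kh + k * kw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = xc[hi + (size_t)H * wi];
            col(row, ho + (size_t)Ho * wo) = v;
          }
        }
      }
    }
  }
}

static void col2im_add(const mat& col, double* dx, int H, int W, int C, int k,
                       int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int row = kh + k * kw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += col(row, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_forward(Rcpp::NumericVector x,
                                   Rcpp::NumericVector wgt,
                                   Rcpp::NumericVector bias,
                                   int stride, int pad) {
  Rcpp::IntegerVector xd = x.attr("dim");
  Rcpp::IntegerVector wd = wgt.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  if (wd[2] != C) Rcpp::stop("channel mismatch between input and kernel");
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  size_t kkC = (size_t)k * k * C;

  mat Wm(Cout, kkC);
  const double* wp = wgt.begin();
  for (int co = 0; co < Cout; ++co)
    for (size_t r = 0; r < kkC; ++r)
      Wm(co, r) = wp[r + kkC * co];
  vec bv(bias.begin(), Cout);

  Rcpp::NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, Cout, N);
  mat col(kkC, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad,
           col, Ho, Wo);
    mat ym = Wm * col;
    ym.each_col() += bv;
    double* yp = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c)
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        yp[p + (size_t)Ho * Wo * c] = ym(c, p);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(Rcpp::NumericVector x, Rcpp::NumericVector wgt,
                           Rcpp::NumericVector dy, int stride, int pad) {
  Rcpp::IntegerVector xd = x.attr("dim");
  Rcpp::IntegerVector wd = wgt.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  size_t kkC = (size_t)k * k * C;

  mat Wm(Cout, kkC);
  const double* wp = wgt.begin();
  for (int co = 0; co < Cout; ++co)
    for (size_t r = 0; r < kkC; ++r)
      Wm(co, r) = wp[r + kkC * co];

  mat dWm(Cout, kkC, fill::zeros);
  vec db(Cout, fill::zeros);
  Rcpp::NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  mat col(kkC, (size_t)Ho * Wo);
  mat dym(Cout, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad,
           col, Ho, Wo);
    const double* dyp = dy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c)
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        dym(c, p) = dyp[p + (size_t)Ho * Wo * c];
    dWm += dym * col.t();
    db += sum(dym, 1);
    mat dcol = Wm.t() * dym;
    col2im_add(dcol, dx.begin() + (size_t)H * W * C * n, H, W, C, k,
               stride, pad, Ho, Wo);
  }

  Rcpp::NumericVector dwgt((R_xlen_t)k * k * C * Cout);
  dwgt.attr("dim") = Rcpp::IntegerVector::create(k, k, C, Cout);
  double* dwp = dwgt.begin();
  for (int co = 0; co < Cout; ++co)
    for (size_t r = 0; r < kkC; ++r)
      dwp[r + kkC * co] = dWm(co, r);

  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dwgt,
                            Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}
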
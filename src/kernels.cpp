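// Compute kernels for the network forward/backward passes.
//
// Tensors arrive from R as numeric arrays with dim (N, H, W, C) in
// column-major order, i.e. element (n, i, j, c) sits at
// n + N*(i + H*(j + W*c)). Convolutions are lowered to a single BLAS GEMM
// through im2col; im2col is recomputed in the backward pass instead of
// cached, trading a little arithmetic for a much smaller live set.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void dims4(const IntegerVector& d, int& n, int& h, int& w, int& c) {
  n = d[0]; h = d[1]; w = d[2]; c = d[3];
}

// cols: (N*H*W) x (k*k*C); tap t = ti + k*tj walks offsets
// (di, dj) = dilation * (ti - k/2, tj - k/2), ti fastest (column-major taps)
static void im2col_fill(const double* x, int N, int H, int W, int C,
                        int k, int dil, arma::mat& cols) {
  const int half = k / 2;
  cols.zeros();
  // for a fixed (tap, channel, output column j) the valid i-run is
  // contiguous in both source and destination: one memcpy of N * run
  const int i_lo0 = 0, i_hi0 = H - 1;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)N * H * W * c;
    for (int tj = 0; tj < k; ++tj) {
      for (int ti = 0; ti < k; ++ti) {
        const int di = dil * (ti - half), dj = dil * (tj - half);
        const int i_lo = std::max(i_lo0, -di), i_hi = std::min(i_hi0, H - 1 - di);
        if (i_lo > i_hi) continue;
        const std::size_t run = (std::size_t)N * (i_hi - i_lo + 1);
        const int t = ti + k * tj;
        double* dst0 = cols.colptr((std::size_t)t * C + c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          std::memcpy(dst0 + (std::size_t)N * (i_lo + (std::size_t)H * j),
                      xc + (std::size_t)N * ((i_lo + di) + (std::size_t)H * sj),
                      sizeof(double) * run);
        }
      }
    }
  }
}

// scatter-add transpose of im2col_fill
static void col2im_add(const arma::mat& gcols, int N, int H, int W, int C,
                       int k, int dil, double* gx) {
  const int half = k / 2;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (std::size_t)N * H * W * c;
    for (int tj = 0; tj < k; ++tj) {
      for (int ti = 0; ti < k; ++ti) {
        const int di = dil * (ti - half), dj = dil * (tj - half);
        const int i_lo = std::max(0, -di), i_hi = std::min(H - 1, H - 1 - di);
        if (i_lo > i_hi) continue;
        const std::size_t run = (std::size_t)N * (i_hi - i_lo + 1);
        const int t = ti + k * tj;
        const double* src0 = gcols.colptr((std::size_t)t * C + c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const double* src = src0 + (std::size_t)N * (i_lo + (std::size_t)H * j);
          double* dst = gc + (std::size_t)N * ((i_lo + di) + (std::size_t)H * sj);
          for (std::size_t t2 = 0; t2 < run; ++t2) dst[t2] += src[t2];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(const NumericVector& x, const IntegerVector& xdim,
                             const NumericMatrix& W, const NumericVector& b,
                             int k, int dilation) {
  int N, H, Wd, C;
  dims4(xdim, N, H, Wd, C);
  const int M = N * H * Wd;
  const int Cout = W.ncol();
  const arma::mat Wm(const_cast<double*>(W.begin()), W.nrow(), Cout, false, true);
  NumericVector y(Rcpp::no_init((std::size_t)M * Cout));
  arma::mat Ym(y.begin(), M, Cout, false, true);
  if (k == 1) {
    const arma::mat Xm(const_cast<double*>(x.begin()), M, C, false, true);
    Ym = Xm * Wm;
  } else {
    arma::mat cols(M, (std::size_t)k * k * C);
    im2col_fill(x.begin(), N, H, Wd, C, k, dilation, cols);
    Ym = cols * Wm;
  }
  for (int c = 0; c < Cout; ++c) Ym.col(c) += b[c];
  y.attr("dim") = IntegerVector::create(N, H, Wd, Cout);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const NumericVector& gy, const NumericVector& x,
                    const IntegerVector& xdim, const NumericMatrix& W,
                    int k, int dilation) {
  int N, H, Wd, C;
  dims4(xdim, N, H, Wd, C);
  const int M = N * H * Wd;
  const int Cout = W.ncol();
  const arma::mat Wm(const_cast<double*>(W.begin()), W.nrow(), Cout, false, true);
  const arma::mat Gy(const_cast<double*>(gy.begin()), M, Cout, false, true);

  NumericMatrix gW(W.nrow(), Cout);
  arma::mat gWm(gW.begin(), W.nrow(), Cout, false, true);
  NumericVector gx((std::size_t)M * C);  // zero-initialized
  NumericVector gb(Cout);
  for (int c = 0; c < Cout; ++c) gb[c] = arma::accu(Gy.col(c));

  if (k == 1) {
    const arma::mat Xm(const_cast<double*>(x.begin()), M, C, false, true);
    gWm = Xm.t() * Gy;
    arma::mat Gx(gx.begin(), M, C, false, true);
    Gx = Gy * Wm.t();
  } else {
    arma::mat cols(M, (std::size_t)k * k * C);
    im2col_fill(x.begin(), N, H, Wd, C, k, dilation, cols);
    gWm = cols.t() * Gy;
    arma::mat gcols = Gy * Wm.t();
    col2im_add(gcols, N, H, Wd, C, k, dilation, gx.begin());
  }
  gx.attr("dim") = xdim;
  return List::create(Named("gx") = gx, Named("gW") = gW, Named("gb") = gb);
}

// 2x2 stride-2 transposed convolution; W is C_in x (4*C_out), column blocks
// ordered by output offset (a, b) in {(0,0), (1,0), (0,1), (1,1)}
// [[Rcpp::export]]
NumericVector convt2d_fwd_cpp(const NumericVector& x, const IntegerVector& xdim,
                              const NumericMatrix& W, const NumericVector& b) {
  int N, H, Wd, C;
  dims4(xdim, N, H, Wd, C);
  const int M = N * H * Wd;
  const int Cout = W.ncol() / 4;
  const arma::mat Xm(const_cast<double*>(x.begin()), M, C, false, true);
  const arma::mat Wm(const_cast<double*>(W.begin()), C, W.ncol(), false, true);
  arma::mat Ym = Xm * Wm;  // M x 4*Cout
  const int H2 = 2 * H, W2 = 2 * Wd;
  NumericVector y(Rcpp::no_init((std::size_t)N * H2 * W2 * Cout));
  double* yp = y.begin();
  for (int t = 0; t < 4; ++t) {
    const int a = (t == 1 || t == 3), bb = (t == 2 || t == 3);
    for (int c = 0; c < Cout; ++c) {
      const double* src = Ym.colptr((std::size_t)t * Cout + c);
      double* dst = yp + (std::size_t)N * H2 * W2 * c;
      for (int j = 0; j < Wd; ++j)
        for (int i = 0; i < H; ++i)
          std::memcpy(dst + (std::size_t)N * ((2 * i + a) + (std::size_t)H2 * (2 * j + bb)),
                      src + (std::size_t)N * (i + (std::size_t)H * j),
                      sizeof(double) * N);
    }
  }
  arma::mat Yfull(yp, (std::size_t)N * H2 * W2, Cout, false, true);
  for (int c = 0; c < Cout; ++c) Yfull.col(c) += b[c];
  y.attr("dim") = IntegerVector::create(N, H2, W2, Cout);
  return y;
}

// [[Rcpp::export]]
List convt2d_bwd_cpp(const NumericVector& gy, const NumericVector& x,
                     const IntegerVector& xdim, const NumericMatrix& W) {
  int N, H, Wd, C;
  dims4(xdim, N, H, Wd, C);
  const int M = N * H * Wd;
  const int Cout = W.ncol() / 4;
  const int H2 = 2 * H, W2 = 2 * Wd;
  arma::mat Gym(M, (std::size_t)4 * Cout);
  const double* gp = gy.begin();
  NumericVector gb(Cout);
  for (int t = 0; t < 4; ++t) {
    const int a = (t == 1 || t == 3), bb = (t == 2 || t == 3);
    for (int c = 0; c < Cout; ++c) {
      double* dst = Gym.colptr((std::size_t)t * Cout + c);
      const double* src = gp + (std::size_t)N * H2 * W2 * c;
      for (int j = 0; j < Wd; ++j)
        for (int i = 0; i < H; ++i)
          std::memcpy(dst + (std::size_t)N * (i + (std::size_t)H * j),
                      src + (std::size_t)N * ((2 * i + a) + (std::size_t)H2 * (2 * j + bb)),
                      sizeof(double) * N);
    }
  }
  const arma::mat Gyfull(const_cast<double*>(gp), (std::size_t)N * H2 * W2, Cout, false, true);
  for (int c = 0; c < Cout; ++c) gb[c] = arma::accu(Gyfull.col(c));
  const arma::mat Xm(const_cast<double*>(x.begin()), M, C, false, true);
  const arma::mat Wm(const_cast<double*>(W.begin()), C, W.ncol(), false, true);
  NumericMatrix gW(C, W.ncol());
  arma::mat gWm(gW.begin(), C, W.ncol(), false, true);
  gWm = Xm.t() * Gym;
  NumericVector gx(Rcpp::no_init((std::size_t)M * C));
  arma::mat Gx(gx.begin(), M, C, false, true);
  Gx = Gym * Wm.t();
  gx.attr("dim") = xdim;
  return List::create(Named("gx") = gx, Named("gW") = gW, Named("gb") = gb);
}

// [[Rcpp::export]]
NumericVector maxpool2_fwd_cpp(const NumericVector& x, const IntegerVector& xdim) {
  int N, H, Wd, C;
  dims4(xdim, N, H, Wd, C);
  const int Ho = H / 2, Wo = Wd / 2;
  NumericVector y(Rcpp::no_init((std::size_t)N * Ho * Wo * C));
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const std::size_t o = (std::size_t)N * (i + (std::size_t)Ho * (j + (std::size_t)Wo * c));
        const std::size_t b00 = (std::size_t)N * (2 * i + (std::size_t)H * (2 * j + (std::size_t)Wd * c));
        const std::size_t b10 = b00 + N;
        const std::size_t b01 = b00 + (std::size_t)N * H;
        const std::size_t b11 = b01 + N;
        for (int n = 0; n < N; ++n) {
          double m = xp[b00 + n];
          if (xp[b10 + n] > m) m = xp[b10 + n];
          if (xp[b01 + n] > m) m = xp[b01 + n];
          if (xp[b11 + n] > m) m = xp[b11 + n];
          yp[o + n] = m;
        }
      }
  y.attr("dim") = IntegerVector::create(N, Ho, Wo, C);
  return y;
}

// gradient routed to the first maximal element of each 2x2 window, window
// scan order (0,0), (1,0), (0,1), (1,1)
// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(const NumericVector& gy, const NumericVector& x,
                               const IntegerVector& xdim) {
  int N, H, Wd, C;
  dims4(xdim, N, H, Wd, C);
  const int Ho = H / 2, Wo = Wd / 2;
  NumericVector gx((std::size_t)N * H * Wd * C);  // zeros
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const std::size_t o = (std::size_t)N * (i + (std::size_t)Ho * (j + (std::size_t)Wo * c));
        const std::size_t b00 = (std::size_t)N * (2 * i + (std::size_t)H * (2 * j + (std::size_t)Wd * c));
        const std::size_t off[4] = {b00, b00 + N, b00 + (std::size_t)N * H,
                                    b00 + (std::size_t)N * H + N};
        for (int n = 0; n < N; ++n) {
          int best = 0;
          double m = xp[off[0] + n];
          for (int t = 1; t < 4; ++t)
            if (xp[off[t] + n] > m) { m = xp[off[t] + n]; best = t; }
          gxp[off[best] + n] += gp[o + n];
        }
      }
  gx.attr("dim") = xdim;
  return gx;
}

// batch normalization over (N, H, W) per channel: returns y and, in
// training mode, the batch statistics needed for the backward pass
// [[Rcpp::export]]
List bn_fwd_cpp(const NumericVector& x, const IntegerVector& xdim,
                const NumericVector& gamma, const NumericVector& beta,
                const NumericVector& mean_in, const NumericVector& var_in,
                bool training, double eps) {
  int N, H, Wd, C;
  dims4(xdim, N, H, Wd, C);
  const std::size_t M = (std::size_t)N * H * Wd;
  NumericVector y(Rcpp::no_init(M * C));
  NumericVector xhat(Rcpp::no_init(M * C));
  NumericVector mu(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + M * c;
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (std::size_t t = 0; t < M; ++t) { s += xc[t]; s2 += xc[t] * xc[t]; }
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
    } else {
      m = mean_in[c];
      v = var_in[c];
    }
    mu[c] = m; var[c] = v;
    const double inv = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], bb = beta[c];
    double* yc = y.begin() + M * c;
    double* hc = xhat.begin() + M * c;
    for (std::size_t t = 0; t < M; ++t) {
      const double h = (xc[t] - m) * inv;
      hc[t] = h;
      yc[t] = g * h + bb;
    }
  }
  y.attr("dim") = xdim;
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("mean") = mu, Named("var") = var);
}

// [[Rcpp::export]]
List bn_bwd_cpp(const NumericVector& gy, const NumericVector& xhat,
                const IntegerVector& xdim, const NumericVector& gamma,
                const NumericVector& var, bool training, double eps) {
  int N, H, Wd, C;
  dims4(xdim, N, H, Wd, C);
  const std::size_t M = (std::size_t)N * H * Wd;
  NumericVector gx(Rcpp::no_init(M * C));
  NumericVector ggamma(C), gbeta(C);
  const double* gp = gy.begin();
  const double* hp = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double* gc = gp + M * c;
    const double* hc = hp + M * c;
    double sg = 0, sgh = 0;
    for (std::size_t t = 0; t < M; ++t) { sg += gc[t]; sgh += gc[t] * hc[t]; }
    ggamma[c] = sgh;
    gbeta[c] = sg;
    const double inv = gamma[c] / std::sqrt(var[c] + eps);
    double* gxc = gx.begin() + M * c;
    if (training) {
      const double mg = sg / M, mgh = sgh / M;
      for (std::size_t t = 0; t < M; ++t)
        gxc[t] = inv * (gc[t] - mg - hc[t] * mgh);
    } else {
      for (std::size_t t = 0; t < M; ++t) gxc[t] = inv * gc[t];
    }
  }
  gx.attr("dim") = xdim;
  return List::create(Named("gx") = gx, Named("ggamma") = ggamma,
                      Named("gbeta") = gbeta);
}
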
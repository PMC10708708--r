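// Low-level neural-network primitives (forward + backward) used by the
// R-level layer graph. Tensors are R numeric arrays in column-major
// (H, W, C, N) layout; conv weights are (kh, kw, C, F). Convolution is
// implemented as im2col + BLAS GEMM via Armadillo.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector tensor_dims(const NumericVector &x, int ndim,
                                        const char *what) {
  SEXP d = x.attr("dim");
  if (Rf_isNull(d)) stop("%s: input has no dim attribute", what);
  IntegerVector dims(d);
  if (dims.size() != ndim) stop("%s: expected %d-d array", what, ndim);
  return dims;
}

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather the im2col matrix K (kh*kw*C x Ho*Wo*N). Row index r = ki +
// kh*(kj + kw*c) matches the column-major flattening of the first three
// weight dimensions; column index = ho + Ho*(wo + Wo*n).
static void im2col(const double *x, int H, int W, int C, int N,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int Ho, int Wo, arma::mat &K) {
  const int HW = H * W;
  for (int n = 0; n < N; ++n) {
    const double *xn = x + (size_t)n * C * HW;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * sw - pw;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * sh - ph;
        const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        double *Kcol = K.colptr(col);
        for (int c = 0; c < C; ++c) {
          const double *xc = xn + (size_t)c * HW;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = w0 + kj;
            double *Krow = Kcol + kh * (kj + kw * c);
            if (wi < 0 || wi >= W) {
              for (int ki = 0; ki < kh; ++ki) Krow[ki] = 0.0;
            } else {
              const double *xcol = xc + (size_t)wi * H;
              for (int ki = 0; ki < kh; ++ki) {
                const int hi = h0 + ki;
                Krow[ki] = (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-accumulate of the column gradients back onto the input image
// (reverse of im2col).
static void col2im(const arma::mat &Kg, int H, int W, int C, int N,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int Ho, int Wo, double *dx) {
  const int HW = H * W;
  for (int n = 0; n < N; ++n) {
    double *xn = dx + (size_t)n * C * HW;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * sw - pw;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * sh - ph;
        const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        const double *Kcol = Kg.colptr(col);
        for (int c = 0; c < C; ++c) {
          double *xc = xn + (size_t)c * HW;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = w0 + kj;
            if (wi < 0 || wi >= W) continue;
            const double *Krow = Kcol + kh * (kj + kw * c);
            double *xcol = xc + (size_t)wi * H;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = h0 + ki;
              if (hi >= 0 && hi < H) xcol[hi] += Krow[ki];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int sh, int sw, int ph, int pw) {
  IntegerVector xd = tensor_dims(x, 4, "nn_conv2d_fwd(x)");
  IntegerVector wd = tensor_dims(w, 4, "nn_conv2d_fwd(w)");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("nn_conv2d_fwd: channel mismatch (%d vs %d)", wd[2], C);
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  if (Ho < 1 || Wo < 1) stop("nn_conv2d_fwd: output size would be empty");

  arma::mat K(kh * kw * C, (size_t)Ho * Wo * N);
  im2col(x.begin(), H, W, C, N, kh, kw, sh, sw, ph, pw, Ho, Wo, K);
  arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * C, F, false, true);
  arma::mat Y = Wm.t() * K;  // F x (Ho*Wo*N)

  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * F * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  double *yp = y.begin();
  const double *bp = b.begin();
  const size_t plane = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      double *dst = yp + plane * (f + (size_t)F * n);
      const double bias = bp[f];
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dst[ho + (size_t)Ho * wo] =
              Y(f, (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n)) + bias;
    }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int sh, int sw, int ph, int pw) {
  IntegerVector xd = tensor_dims(x, 4, "nn_conv2d_bwd(x)");
  IntegerVector wd = tensor_dims(w, 4, "nn_conv2d_bwd(w)");
  IntegerVector yd = tensor_dims(dy, 4, "nn_conv2d_bwd(dy)");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = yd[0], Wo = yd[1];

  // repack dy into (F x Ho*Wo*N)
  arma::mat dY(F, (size_t)Ho * Wo * N);
  const double *dyp = dy.begin();
  const size_t plane = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      const double *src = dyp + plane * (f + (size_t)F * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dY(f, (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n)) =
              src[ho + (size_t)Ho * wo];
    }

  arma::mat K(kh * kw * C, (size_t)Ho * Wo * N);
  im2col(x.begin(), H, W, C, N, kh, kw, sh, sw, ph, pw, Ho, Wo, K);

  arma::mat dWm = K * dY.t();  // (kh*kw*C) x F
  NumericVector dw(Rf_allocVector(REALSXP, (R_xlen_t)kh * kw * C * F));
  dw.attr("dim") = IntegerVector::create(kh, kw, C, F);
  std::copy(dWm.begin(), dWm.end(), dw.begin());

  NumericVector db(F);
  arma::vec dbv = arma::sum(dY, 1);
  std::copy(dbv.begin(), dbv.end(), db.begin());

  arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * C, F, false, true);
  arma::mat Kg = Wm * dY;  // (kh*kw*C) x cols
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::fill(dx.begin(), dx.end(), 0.0);
  col2im(Kg, H, W, C, N, kh, kw, sh, sw, ph, pw, Ho, Wo, dx.begin());

  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x, int k, int s, int p) {
  IntegerVector xd = tensor_dims(x, 4, "nn_maxpool_fwd");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  if (Ho < 1 || Wo < 1) stop("nn_maxpool_fwd: output size would be empty");
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 0-based linear index into x of the max
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  const size_t HW = (size_t)H * W;
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = xp + HW * (c + (size_t)C * n);
      const size_t base = HW * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          long bi = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * s - p + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * s - p + ki;
              if (hi < 0 || hi >= H) continue;
              const double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; bi = hi + (long)H * wi; }
            }
          }
          yp[o + (size_t)ho + (size_t)Ho * wo] = best;
          ip[o + (size_t)ho + (size_t)Ho * wo] = (int)(base + bi);
        }
      o += (size_t)Ho * Wo;
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(NumericVector dy, IntegerVector idx,
                             IntegerVector xdim) {
  NumericVector dx(Rf_allocVector(
      REALSXP, (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]));
  dx.attr("dim") = xdim;
  std::fill(dx.begin(), dx.end(), 0.0);
  const double *dyp = dy.begin();
  const int *ip = idx.begin();
  double *dxp = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dxp[ip[i]] += dyp[i];
  return dx;
}

// Average pooling; the divisor is always k*k (padded positions count as
// zeros), matching the usual deep-learning convention.
// [[Rcpp::export]]
NumericVector nn_avgpool_fwd(NumericVector x, int k, int s, int p) {
  IntegerVector xd = tensor_dims(x, 4, "nn_avgpool_fwd");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  if (Ho < 1 || Wo < 1) stop("nn_avgpool_fwd: output size would be empty");
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = x.begin();
  double *yp = y.begin();
  const size_t HW = (size_t)H * W;
  const double inv = 1.0 / (k * k);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = xp + HW * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * s - p + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * s - p + ki;
              if (hi < 0 || hi >= H) continue;
              acc += xc[hi + (size_t)H * wi];
            }
          }
          yp[o + (size_t)ho + (size_t)Ho * wo] = acc * inv;
        }
      o += (size_t)Ho * Wo;
    }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_avgpool_bwd(NumericVector dy, IntegerVector xdim,
                             int k, int s, int p) {
  IntegerVector yd = tensor_dims(dy, 4, "nn_avgpool_bwd");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  dx.attr("dim") = xdim;
  std::fill(dx.begin(), dx.end(), 0.0);
  const double *dyp = dy.begin();
  double *dxp = dx.begin();
  const size_t HW = (size_t)H * W;
  const double inv = 1.0 / (k * k);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *xc = dxp + HW * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = dyp[o + (size_t)ho + (size_t)Ho * wo] * inv;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * s - p + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * s - p + ki;
              if (hi < 0 || hi >= H) continue;
              xc[hi + (size_t)H * wi] += g;
            }
          }
        }
      o += (size_t)Ho * Wo;
    }
  return dx;
}

// Batch normalization over the channel axis of an (H, W, C, N) tensor.
// In training mode the batch statistics (biased variance) are used and
// the running estimates updated in place with the given momentum.
// [[Rcpp::export]]
List nn_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector rmean, NumericVector rvar,
               double eps, double momentum, bool training) {
  IntegerVector xd = tensor_dims(x, 4, "nn_bn_fwd");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W, m = HW * N;
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = xd;
  NumericVector bmean(C), bvar(C);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      double acc = 0.0, acc2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double *xc = xp + HW * (c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i) { acc += xc[i]; acc2 += xc[i] * xc[i]; }
      }
      mu = acc / m;
      var = acc2 / m - mu * mu;
      if (var < 0) var = 0;
      bmean[c] = mu; bvar[c] = var;
      rmean[c] = (1 - momentum) * rmean[c] + momentum * mu;
      rvar[c] = (1 - momentum) * rvar[c] + momentum * var;
    } else {
      mu = rmean[c]; var = rvar[c];
      bmean[c] = mu; bvar[c] = var;
    }
    const double inv = 1.0 / std::sqrt(var + eps);
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double *xc = xp + HW * (c + (size_t)C * n);
      double *yc = yp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yc[i] = g * (xc[i] - mu) * inv + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = bmean, _["var"] = bvar);
}

// [[Rcpp::export]]
List nn_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
               NumericVector mean, NumericVector var, double eps) {
  IntegerVector xd = tensor_dims(x, 4, "nn_bn_bwd");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W, m = HW * N;
  NumericVector dx(Rf_allocVector(REALSXP, x.size()));
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  const double *xp = x.begin(), *dyp = dy.begin();
  double *dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c];
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    double sum_dy = 0.0, sum_dy_xhat = 0.0;
    for (int n = 0; n < N; ++n) {
      const double *xc = xp + HW * (c + (size_t)C * n);
      const double *dc = dyp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        const double xh = (xc[i] - mu) * inv;
        sum_dy += dc[i];
        sum_dy_xhat += dc[i] * xh;
      }
    }
    dgamma[c] = sum_dy_xhat;
    dbeta[c] = sum_dy;
    const double g = gamma[c];
    const double mean_dy = sum_dy / m, mean_dy_xhat = sum_dy_xhat / m;
    for (int n = 0; n < N; ++n) {
      const double *xc = xp + HW * (c + (size_t)C * n);
      const double *dc = dyp + HW * (c + (size_t)C * n);
      double *dxc = dxp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        const double xh = (xc[i] - mu) * inv;
        dxc[i] = g * inv * (dc[i] - mean_dy - xh * mean_dy_xhat);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
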
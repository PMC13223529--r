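// Low-level numerical kernels for 2D segmentation networks.
// Array layout throughout: column-major R arrays dim = c(H, W, C, N)
// (height, width, channels, batch); weights dim = c(k, k, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col, transposed layout: M is (Ho*Wo) x (k*k*Cin), so each column holds
// one (kh, kw, c) patch-offset over all output pixels and is filled with
// contiguous runs along h when stride == 1.
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, arma::mat& M) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  M.zeros((size_t)Ho * Wo, (size_t)k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* mcol = M.colptr(kh + k * kw + (size_t)k * k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (size_t)H * wi;
          double* mc = mcol + (size_t)Ho * wo;
          if (stride == 1) {
            const int h_lo = std::max(0, pad - kh);
            const int h_hi = std::min(Ho, H + pad - kh);
            if (h_hi > h_lo)
              std::memcpy(mc + h_lo, xcol + h_lo - pad + kh,
                          (size_t)(h_hi - h_lo) * sizeof(double));
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + kh;
              if (hi >= 0 && hi < H) mc[ho] = xcol[hi];
            }
          }
        }
      }
    }
  }
}

// scatter-add of the transposed column matrix back to the image
static void col2im(const arma::mat& M, int H, int W, int C,
                   int k, int stride, int pad, double* dx) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* mcol = M.colptr(kh + k * kw + (size_t)k * k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)H * wi;
          const double* mc = mcol + (size_t)Ho * wo;
          if (stride == 1) {
            const int h_lo = std::max(0, pad - kh);
            const int h_hi = std::min(Ho, H + pad - kh);
            for (int ho = h_lo; ho < h_hi; ++ho)
              xcol[ho - pad + kh] += mc[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + kh;
              if (hi >= 0 && hi < H) xcol[hi] += mc[ho];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::mat M;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, M);
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout, false, true);
    Y = M * Wm;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd; dw.attr("dim") = wd;
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), k * k * Cin, Cout, false, true);
  arma::mat M;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, M);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                 Ho * Wo, Cout, false, true);
    dWm += M.t() * dY;
    arma::mat dM = dY * Wm.t();
    col2im(dM, H, W, C, k, stride, pad, dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Non-overlapping max pooling with window f; H, W must be divisible by f.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int f) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % f != 0 || W % f != 0)
    stop("maxpool: spatial size %dx%d not divisible by window %d", H, W, f);
  const int Ho = H / f, Wo = W / f;
  NumericVector y(Ho * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t p = 0, P = (size_t)C * N; p < P; ++p) {
    const double* xp = x.begin() + (size_t)H * W * p;
    double* yp = y.begin() + (size_t)Ho * Wo * p;
    int* ip = idx.begin() + (size_t)Ho * Wo * p;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -std::numeric_limits<double>::infinity(); int bi = 0;
        for (int dw = 0; dw < f; ++dw)
          for (int dh = 0; dh < f; ++dh) {
            const int hi = ho * f + dh, wi = wo * f + dw;
            const double v = xp[hi + (size_t)H * wi];
            if (v > best) { best = v; bi = hi + H * wi; }
          }
        yp[ho + Ho * wo] = best;
        ip[ho + Ho * wo] = bi;
      }
  }
  idx.attr("dim") = y.attr("dim");
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t p = 0, P = (size_t)C * N; p < P; ++p) {
    const double* dyp = dy.begin() + (size_t)Ho * Wo * p;
    const int* ip = idx.begin() + (size_t)Ho * Wo * p;
    double* dxp = dx.begin() + (size_t)H * W * p;
    for (int q = 0; q < Ho * Wo; ++q) dxp[ip[q]] += dyp[q];
  }
  return dx;
}

// Bilinear resize to (Ho, Wo), half-pixel centers (align_corners = FALSE).
static void bilinear_coeffs(int in, int out, std::vector<int>& i0,
                            std::vector<int>& i1, std::vector<double>& a) {
  i0.resize(out); i1.resize(out); a.resize(out);
  const double s = (double)in / out;
  for (int o = 0; o < out; ++o) {
    double src = (o + 0.5) * s - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    i0[o] = (int)std::floor(src);
    i1[o] = std::min(i0[o] + 1, in - 1);
    a[o] = src - i0[o];
  }
}

// [[Rcpp::export]]
NumericVector bilinear_fwd_cpp(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> h0, h1, w0, w1; std::vector<double> ah, aw;
  bilinear_coeffs(H, Ho, h0, h1, ah);
  bilinear_coeffs(W, Wo, w0, w1, aw);
  for (size_t p = 0, P = (size_t)C * N; p < P; ++p) {
    const double* xp = x.begin() + (size_t)H * W * p;
    double* yp = y.begin() + (size_t)Ho * Wo * p;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double v00 = xp[h0[ho] + (size_t)H * w0[wo]];
        const double v10 = xp[h1[ho] + (size_t)H * w0[wo]];
        const double v01 = xp[h0[ho] + (size_t)H * w1[wo]];
        const double v11 = xp[h1[ho] + (size_t)H * w1[wo]];
        yp[ho + (size_t)Ho * wo] =
          (1 - ah[ho]) * ((1 - aw[wo]) * v00 + aw[wo] * v01) +
          ah[ho] * ((1 - aw[wo]) * v10 + aw[wo] * v11);
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector bilinear_bwd_cpp(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> h0, h1, w0, w1; std::vector<double> ah, aw;
  bilinear_coeffs(H, Ho, h0, h1, ah);
  bilinear_coeffs(W, Wo, w0, w1, aw);
  for (size_t p = 0, P = (size_t)C * N; p < P; ++p) {
    const double* dyp = dy.begin() + (size_t)Ho * Wo * p;
    double* dxp = dx.begin() + (size_t)H * W * p;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dyp[ho + (size_t)Ho * wo];
        dxp[h0[ho] + (size_t)H * w0[wo]] += (1 - ah[ho]) * (1 - aw[wo]) * g;
        dxp[h1[ho] + (size_t)H * w0[wo]] += ah[ho] * (1 - aw[wo]) * g;
        dxp[h0[ho] + (size_t)H * w1[wo]] += (1 - ah[ho]) * aw[wo] * g;
        dxp[h1[ho] + (size_t)H * w1[wo]] += ah[ho] * aw[wo] * g;
      }
  }
  return dx;
}

// Batch normalization without learnable affine parameters.
// Statistics are taken per channel over (H, W, N).
// [[Rcpp::export]]
List batchnorm_fwd_cpp(NumericVector x, NumericVector run_mean,
                       NumericVector run_var, double momentum, double eps,
                       bool training) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t S = (size_t)H * W;
  NumericVector y(x.size()); y.attr("dim") = xd;
  NumericVector mean(C), invstd(C), new_rm(clone(run_mean)), new_rv(clone(run_var));
  const double M = (double)S * N;
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + S * (c + (size_t)C * n);
        for (size_t q = 0; q < S; ++q) { s += xp[q]; s2 += xp[q] * xp[q]; }
      }
      mu = s / M;
      var = s2 / M - mu * mu;
      if (var < 0) var = 0;
      new_rm[c] = (1 - momentum) * run_mean[c] + momentum * mu;
      // unbiased variance in the running estimate
      new_rv[c] = (1 - momentum) * run_var[c] +
                  momentum * (M > 1 ? var * M / (M - 1) : var);
    } else {
      mu = run_mean[c]; var = run_var[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    mean[c] = mu; invstd[c] = is;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + S * (c + (size_t)C * n);
      double* yp = y.begin() + S * (c + (size_t)C * n);
      for (size_t q = 0; q < S; ++q) yp[q] = (xp[q] - mu) * is;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd,
                      _["run_mean"] = new_rm, _["run_var"] = new_rv);
}

// [[Rcpp::export]]
NumericVector batchnorm_bwd_cpp(NumericVector dy, NumericVector x,
                                NumericVector mean, NumericVector invstd,
                                bool training) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t S = (size_t)H * W;
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  const double M = (double)S * N;
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c];
    if (!training) {  // running stats are constants
      for (int n = 0; n < N; ++n) {
        const double* dyp = dy.begin() + S * (c + (size_t)C * n);
        double* dxp = dx.begin() + S * (c + (size_t)C * n);
        for (size_t q = 0; q < S; ++q) dxp[q] = dyp[q] * is;
      }
      continue;
    }
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const double* dyp = dy.begin() + S * (c + (size_t)C * n);
      const double* xp = x.begin() + S * (c + (size_t)C * n);
      for (size_t q = 0; q < S; ++q) {
        sdy += dyp[q];
        sdyx += dyp[q] * (xp[q] - mu) * is;
      }
    }
    for (int n = 0; n < N; ++n) {
      const double* dyp = dy.begin() + S * (c + (size_t)C * n);
      const double* xp = x.begin() + S * (c + (size_t)C * n);
      double* dxp = dx.begin() + S * (c + (size_t)C * n);
      for (size_t q = 0; q < S; ++q) {
        const double xh = (xp[q] - mu) * is;
        dxp[q] = is * (dyp[q] - sdy / M - xh * sdyx / M);
      }
    }
  }
  return dx;
}
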
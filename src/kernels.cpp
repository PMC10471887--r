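// Dense compute kernels for the convolutional engine.
//
// Tensor layout throughout: 4-d arrays with dim (C, H, W, N), channel fastest.
// Convolution weights: matrix (K x Cout) with K = Cin*kh*kw and row index
// c + Cin*(ki + kh*kj)  (ki = row offset, kj = column offset of the tap).
// This makes im2col a sequence of C-length memcpys and turns the convolution
// into one BLAS gemm per batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Reusable workspaces for the im2col buffers: layer shapes repeat every
// batch, and letting glibc hand ~20-40 MB blocks back to the OS after each
// convolution costs more than the gemm itself. Grown monotonically, never
// shrunk; R is single-threaded so plain statics are safe.
static std::vector<double>& workspace(int which, size_t n) {
  static std::vector<double> buf[2];
  if (buf[which].size() < n) buf[which].resize(n);
  return buf[which];
}

// Fill col (K x L), L = oH*oW*N, column l = oh + oH*(ow + oW*n).
static void im2col(const double* x, int C, int H, int W, int N,
                   int kh, int kw, int stride, int pad, arma::mat& col) {
  const int oH = out_extent(H, kh, stride, pad);
  const int oW = out_extent(W, kw, stride, pad);
  const size_t K = (size_t)C * kh * kw;
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * C * H * W;
    for (int ow = 0; ow < oW; ++ow) {
      const int w0 = ow * stride - pad;
      for (int oh = 0; oh < oH; ++oh) {
        const int h0 = oh * stride - pad;
        double* dst = col.colptr((size_t)oh + (size_t)oH * (ow + (size_t)oW * n));
        for (int kj = 0; kj < kw; ++kj) {
          const int w = w0 + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = h0 + ki;
            double* d = dst + (size_t)C * (ki + kh * kj);
            if (h >= 0 && h < H && w >= 0 && w < W) {
              std::memcpy(d, xn + ((size_t)w * H + h) * C, C * sizeof(double));
            } else {
              std::memset(d, 0, C * sizeof(double));
            }
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2col.
static void col2im(const arma::mat& col, int C, int H, int W, int N,
                   int kh, int kw, int stride, int pad, double* dx) {
  const int oH = out_extent(H, kh, stride, pad);
  const int oW = out_extent(W, kw, stride, pad);
  for (int n = 0; n < N; ++n) {
    double* xn = dx + (size_t)n * C * H * W;
    for (int ow = 0; ow < oW; ++ow) {
      const int w0 = ow * stride - pad;
      for (int oh = 0; oh < oH; ++oh) {
        const int h0 = oh * stride - pad;
        const double* src = col.colptr((size_t)oh + (size_t)oH * (ow + (size_t)oW * n));
        for (int kj = 0; kj < kw; ++kj) {
          const int w = w0 + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = h0 + ki;
            if (h < 0 || h >= H) continue;
            double* d = xn + ((size_t)w * H + h) * C;
            const double* s = src + (size_t)C * (ki + kh * kj);
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xdim,
                           NumericMatrix weight, SEXP bias,
                           int kh, int kw, int stride, int pad) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int oH = out_extent(H, kh, stride, pad);
  const int oW = out_extent(W, kw, stride, pad);
  const size_t K = (size_t)C * kh * kw;
  const int Cout = weight.ncol();
  if ((size_t)weight.nrow() != K)
    stop("conv weight rows (%d) do not match Cin*kh*kw (%d)", weight.nrow(), (int)K);
  const size_t L = (size_t)oH * oW * N;
  arma::mat col(workspace(0, K * L).data(), K, L, false, true);
  im2col(x.begin(), C, H, W, N, kh, kw, stride, pad, col);
  arma::mat Wm(weight.begin(), K, Cout, false, true);
  NumericVector out((size_t)Cout * L);
  arma::mat Y(out.begin(), Cout, L, false, true);
  Y = Wm.t() * col;  // Cout x L
  if (!Rf_isNull(bias)) {
    NumericVector b(bias);
    arma::colvec bv(b.begin(), Cout, false, true);
    Y.each_col() += bv;
  }
  out.attr("dim") = IntegerVector::create(Cout, oH, oW, N);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(NumericVector x, IntegerVector xdim,
                  NumericMatrix weight, NumericVector dy,
                  int kh, int kw, int stride, int pad,
                  bool has_bias, bool need_dx) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int oH = out_extent(H, kh, stride, pad);
  const int oW = out_extent(W, kw, stride, pad);
  const size_t K = (size_t)C * kh * kw;
  const int Cout = weight.ncol();
  const size_t L = (size_t)oH * oW * N;
  arma::mat col(workspace(0, K * L).data(), K, L, false, true);
  im2col(x.begin(), C, H, W, N, kh, kw, stride, pad, col);
  arma::mat dY(dy.begin(), Cout, L, false, true);
  NumericMatrix dWout(K, Cout);
  arma::mat dW(dWout.begin(), K, Cout, false, true);
  dW = col * dY.t();  // K x Cout
  List res = List::create(Named("dW") = dWout);
  if (has_bias) {
    arma::colvec db = arma::sum(dY, 1);
    res["db"] = NumericVector(db.begin(), db.end());
  }
  if (need_dx) {
    arma::mat Wm(weight.begin(), K, Cout, false, true);
    arma::mat dcol(workspace(1, K * L).data(), K, L, false, true);
    dcol = Wm * dY;  // K x L
    NumericVector dx((size_t)C * H * W * N);
    col2im(dcol, C, H, W, N, kh, kw, stride, pad, dx.begin());
    dx.attr("dim") = xdim;
    res["dx"] = dx;
  }
  return res;
}

// [[Rcpp::export(name = ".cpp_maxpool_fwd")]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim,
                     int k, int stride, int pad) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int oH = out_extent(H, k, stride, pad);
  const int oW = out_extent(W, k, stride, pad);
  const size_t n_out = (size_t)C * oH * oW * N;
  NumericVector y(n_out);
  IntegerVector idx(n_out);  // 0-based linear index into x
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    const size_t xoff = (size_t)n * C * H * W;
    for (int ow = 0; ow < oW; ++ow) {
      const int w0 = ow * stride - pad;
      for (int oh = 0; oh < oH; ++oh) {
        const int h0 = oh * stride - pad;
        const size_t o = (size_t)C * (oh + (size_t)oH * (ow + (size_t)oW * n));
        for (int c = 0; c < C; ++c) {
          double best = -HUGE_VAL;
          size_t best_i = 0;
          for (int kj = 0; kj < k; ++kj) {
            const int w = w0 + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int h = h0 + ki;
              if (h < 0 || h >= H) continue;
              const size_t i = xoff + ((size_t)w * H + h) * C + c;
              if (xp[i] > best) { best = xp[i]; best_i = i; }
            }
          }
          yp[o + c] = best;
          ip[o + c] = (int)best_i;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, oH, oW, N);
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_bwd")]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              IntegerVector xdim) {
  size_t n_in = 1;
  for (int d = 0; d < xdim.size(); ++d) n_in *= (size_t)xdim[d];
  NumericVector dx(n_in);
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  const size_t n_out = dy.size();
  for (size_t i = 0; i < n_out; ++i) dxp[ip[i]] += dyp[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Batch normalization over channels of a (C, H, W, N) tensor. Training mode
// normalizes with biased batch statistics and returns the cache needed for
// the backward pass plus updated running statistics (unbiased variance).
// [[Rcpp::export(name = ".cpp_bn_fwd")]]
List cpp_bn_fwd(NumericVector x, IntegerVector xdim,
                NumericVector gamma, NumericVector beta,
                NumericVector run_mean, NumericVector run_var,
                bool train, double momentum, double eps) {
  const int C = xdim[0];
  const size_t L = (size_t)xdim[1] * xdim[2] * xdim[3];
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  std::vector<double> mu(C), inv(C);
  NumericVector rm_new, rv_new;
  if (train) {
    rm_new = clone(run_mean);  // never mutate the caller's state in place
    rv_new = clone(run_var);
    std::vector<double> s1(C, 0.0), s2(C, 0.0);
    for (size_t i = 0; i < L; ++i) {
      const double* xi = xp + i * C;
      for (int c = 0; c < C; ++c) { s1[c] += xi[c]; s2[c] += xi[c] * xi[c]; }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] = s1[c] / L;
      double va = s2[c] / L - mu[c] * mu[c];
      if (va < 0) va = 0;
      inv[c] = 1.0 / std::sqrt(va + eps);
      double unbiased = (L > 1) ? va * (double)L / (L - 1) : va;
      rm_new[c] = (1 - momentum) * rm_new[c] + momentum * mu[c];
      rv_new[c] = (1 - momentum) * rv_new[c] + momentum * unbiased;
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = run_mean[c];
      inv[c] = 1.0 / std::sqrt(run_var[c] + eps);
    }
  }
  std::vector<double> a(C), b(C);
  for (int c = 0; c < C; ++c) {
    a[c] = gamma[c] * inv[c];
    b[c] = beta[c] - a[c] * mu[c];
  }
  for (size_t i = 0; i < L; ++i) {
    const double* xi = xp + i * C;
    double* yi = yp + i * C;
    for (int c = 0; c < C; ++c) yi[c] = a[c] * xi[c] + b[c];
  }
  y.attr("dim") = xdim;
  List res = List::create(Named("y") = y);
  if (train) {
    res["mu"] = NumericVector(mu.begin(), mu.end());
    res["inv"] = NumericVector(inv.begin(), inv.end());
    res["run_mean"] = rm_new;
    res["run_var"] = rv_new;
  }
  return res;
}

// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector x, IntegerVector xdim, NumericVector dy,
                NumericVector gamma, NumericVector mu, NumericVector inv) {
  const int C = xdim[0];
  const size_t L = (size_t)xdim[1] * xdim[2] * xdim[3];
  const double* xp = x.begin();
  const double* dp = dy.begin();
  std::vector<double> sdy(C, 0.0), sdyx(C, 0.0);
  for (size_t i = 0; i < L; ++i) {
    const double* xi = xp + i * C;
    const double* di = dp + i * C;
    for (int c = 0; c < C; ++c) {
      const double xhat = (xi[c] - mu[c]) * inv[c];
      sdy[c] += di[c];
      sdyx[c] += di[c] * xhat;
    }
  }
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) { dgamma[c] = sdyx[c]; dbeta[c] = sdy[c]; }
  for (size_t i = 0; i < L; ++i) {
    const double* xi = xp + i * C;
    const double* di = dp + i * C;
    double* oi = dxp + i * C;
    for (int c = 0; c < C; ++c) {
      const double xhat = (xi[c] - mu[c]) * inv[c];
      oi[c] = gamma[c] * inv[c] / L * (L * di[c] - sdy[c] - xhat * sdyx[c]);
    }
  }
  dx.attr("dim") = xdim;
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// [[Rcpp::export(name = ".cpp_relu_fwd")]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_bwd")]]
NumericVector cpp_relu_bwd(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  const double* xp = x.begin();
  const double* dp = dy.begin();
  double* op = dx.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? dp[i] : 0.0;
  dx.attr("dim") = x.attr("dim");
  return dx;
}

// Global average pool (C,H,W,N) -> (C,N).
// [[Rcpp::export(name = ".cpp_gap_fwd")]]
NumericMatrix cpp_gap_fwd(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], N = xdim[3];
  const size_t HW = (size_t)xdim[1] * xdim[2];
  NumericMatrix y(C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * C * HW;
    double* yn = &y(0, n);
    for (size_t i = 0; i < HW; ++i) {
      const double* xi = xn + i * C;
      for (int c = 0; c < C; ++c) yn[c] += xi[c];
    }
    for (int c = 0; c < C; ++c) yn[c] /= (double)HW;
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_gap_bwd")]]
NumericVector cpp_gap_bwd(NumericMatrix dy, IntegerVector xdim) {
  const int C = xdim[0], N = xdim[3];
  const size_t HW = (size_t)xdim[1] * xdim[2];
  NumericVector dx((size_t)C * HW * N);
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    double* xn = dxp + (size_t)n * C * HW;
    const double* dn = &dy(0, n);
    for (size_t i = 0; i < HW; ++i) {
      double* xi = xn + i * C;
      for (int c = 0; c < C; ++c) xi[c] = dn[c] / (double)HW;
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}
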
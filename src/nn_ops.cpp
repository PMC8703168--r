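// Compiled kernels for the network engine: im2col/col2im for 1-D and
// 2-D same-padded convolutions, max pooling with argmax bookkeeping,
// and batch-normalization element passes. Arrays are channels-last,
// column-major (R layout): x[b, i, j, c] sits at b + B*(i + H*(j + W*c)).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- 1-D convolution ------------------------------------------------------

// [[Rcpp::export(name = ".im2col1d_cpp")]]
arma::mat im2col1d_cpp(const arma::vec& x, int B, int L, int C, int k) {
  int p = (k - 1) / 2;
  arma::mat M(B * L, k * C);
  for (int o = 0; o < k; ++o) {
    for (int c = 0; c < C; ++c) {
      double* dst = M.colptr(o * C + c);
      const double* src = x.memptr() + (size_t)B * L * c;
      for (int i = 0; i < L; ++i) {
        int ii = i + o - p;
        double* d = dst + (size_t)B * i;
        if (ii < 0 || ii >= L) {
          std::fill(d, d + B, 0.0);
        } else {
          std::copy(src + (size_t)B * ii, src + (size_t)B * (ii + 1), d);
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".col2im1d_cpp")]]
arma::vec col2im1d_cpp(const arma::mat& dM, int B, int L, int C, int k) {
  int p = (k - 1) / 2;
  arma::vec dx((size_t)B * L * C, arma::fill::zeros);
  for (int o = 0; o < k; ++o) {
    for (int c = 0; c < C; ++c) {
      const double* src = dM.colptr(o * C + c);
      double* dst = dx.memptr() + (size_t)B * L * c;
      for (int i = 0; i < L; ++i) {
        int ii = i + o - p;
        if (ii < 0 || ii >= L) continue;
        const double* s = src + (size_t)B * i;
        double* d = dst + (size_t)B * ii;
        for (int b = 0; b < B; ++b) d[b] += s[b];
      }
    }
  }
  return dx;
}

// ---- 2-D convolution ------------------------------------------------------

// [[Rcpp::export(name = ".im2col2d_cpp")]]
arma::mat im2col2d_cpp(const arma::vec& x, int B, int H, int W, int C, int k) {
  int p = (k - 1) / 2;
  arma::mat M((size_t)B * H * W, (size_t)k * k * C);
  int blk = 0;
  for (int oj = 0; oj < k; ++oj) {
    for (int oi = 0; oi < k; ++oi, ++blk) {
      for (int c = 0; c < C; ++c) {
        double* dst = M.colptr((size_t)blk * C + c);
        const double* src = x.memptr() + (size_t)B * H * W * c;
        for (int j = 0; j < W; ++j) {
          int jj = j + oj - p;
          for (int i = 0; i < H; ++i) {
            int ii = i + oi - p;
            double* d = dst + (size_t)B * (i + (size_t)H * j);
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) {
              std::fill(d, d + B, 0.0);
            } else {
              const double* s = src + (size_t)B * (ii + (size_t)H * jj);
              std::copy(s, s + B, d);
            }
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".col2im2d_cpp")]]
arma::vec col2im2d_cpp(const arma::mat& dM, int B, int H, int W, int C, int k) {
  int p = (k - 1) / 2;
  arma::vec dx((size_t)B * H * W * C, arma::fill::zeros);
  int blk = 0;
  for (int oj = 0; oj < k; ++oj) {
    for (int oi = 0; oi < k; ++oi, ++blk) {
      for (int c = 0; c < C; ++c) {
        const double* src = dM.colptr((size_t)blk * C + c);
        double* dst = dx.memptr() + (size_t)B * H * W * c;
        for (int j = 0; j < W; ++j) {
          int jj = j + oj - p;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int ii = i + oi - p;
            if (ii < 0 || ii >= H) continue;
            const double* s = src + (size_t)B * (i + (size_t)H * j);
            double* d = dst + (size_t)B * (ii + (size_t)H * jj);
            for (int b = 0; b < B; ++b) d[b] += s[b];
          }
        }
      }
    }
  }
  return dx;
}

// ---- max pooling ----------------------------------------------------------

// 1-D pooling treated as 2-D with W = 1 handled separately for clarity

// [[Rcpp::export(name = ".pool1d_fwd_cpp")]]
List pool1d_fwd_cpp(const arma::vec& x, int B, int L, int C, int s) {
  int L2 = (L + s - 1) / s;
  arma::vec out((size_t)B * L2 * C);
  IntegerVector arg((size_t)B * L2 * C);
  for (int c = 0; c < C; ++c) {
    for (int i2 = 0; i2 < L2; ++i2) {
      for (int b = 0; b < B; ++b) {
        double best = -arma::datum::inf; int bo = 0;
        for (int o = 0; o < s; ++o) {
          int i = i2 * s + o;
          if (i >= L) break;
          double v = x[(size_t)b + B * ((size_t)i + (size_t)L * c)];
          if (v > best) { best = v; bo = o; }
        }
        size_t at = (size_t)b + B * ((size_t)i2 + (size_t)L2 * c);
        out[at] = best; arg[at] = bo;
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg, _["L2"] = L2);
}

// [[Rcpp::export(name = ".pool1d_bwd_cpp")]]
arma::vec pool1d_bwd_cpp(const arma::vec& dout, const IntegerVector& arg,
                         int B, int L, int C, int s) {
  int L2 = (L + s - 1) / s;
  arma::vec dx((size_t)B * L * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int i2 = 0; i2 < L2; ++i2) {
      for (int b = 0; b < B; ++b) {
        size_t at = (size_t)b + B * ((size_t)i2 + (size_t)L2 * c);
        int i = i2 * s + arg[at];
        dx[(size_t)b + B * ((size_t)i + (size_t)L * c)] += dout[at];
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".pool2d_fwd_cpp")]]
List pool2d_fwd_cpp(const arma::vec& x, int B, int H, int W, int C, int s) {
  int H2 = (H + s - 1) / s, W2 = (W + s - 1) / s;
  arma::vec out((size_t)B * H2 * W2 * C);
  IntegerVector arg((size_t)B * H2 * W2 * C);
  for (int c = 0; c < C; ++c) {
    for (int j2 = 0; j2 < W2; ++j2) {
      for (int i2 = 0; i2 < H2; ++i2) {
        for (int b = 0; b < B; ++b) {
          double best = -arma::datum::inf; int bo = 0, o = 0;
          for (int oj = 0; oj < s; ++oj) {
            int j = j2 * s + oj;
            for (int oi = 0; oi < s; ++oi, ++o) {
              int i = i2 * s + oi;
              if (i >= H || j >= W) continue;
              double v = x[(size_t)b + B * ((size_t)i + H * ((size_t)j + (size_t)W * c))];
              if (v > best) { best = v; bo = o; }
            }
          }
          size_t at = (size_t)b + B * ((size_t)i2 + H2 * ((size_t)j2 + (size_t)W2 * c));
          out[at] = best; arg[at] = bo;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg,
                      _["H2"] = H2, _["W2"] = W2);
}

// [[Rcpp::export(name = ".pool2d_bwd_cpp")]]
arma::vec pool2d_bwd_cpp(const arma::vec& dout, const IntegerVector& arg,
                         int B, int H, int W, int C, int s) {
  int H2 = (H + s - 1) / s, W2 = (W + s - 1) / s;
  arma::vec dx((size_t)B * H * W * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j2 = 0; j2 < W2; ++j2) {
      for (int i2 = 0; i2 < H2; ++i2) {
        for (int b = 0; b < B; ++b) {
          size_t at = (size_t)b + B * ((size_t)i2 + H2 * ((size_t)j2 + (size_t)W2 * c));
          int o = arg[at];
          int oi = o % s, oj = o / s;
          int i = i2 * s + oi, j = j2 * s + oj;
          dx[(size_t)b + B * ((size_t)i + H * ((size_t)j + (size_t)W * c))] += dout[at];
        }
      }
    }
  }
  return dx;
}

// ---- fused convolution forward/backward -----------------------------------

// [[Rcpp::export(name = ".conv1d_fwd_cpp")]]
List conv1d_fwd_cpp(const arma::vec& x, int B, int L, int C,
                    const arma::mat& W, const arma::vec& b, int k) {
  arma::mat M = im2col1d_cpp(x, B, L, C, k);
  arma::mat out = M * W;
  out.each_row() += b.t();
  return List::create(_["out"] = out, _["M"] = M);
}

// [[Rcpp::export(name = ".conv1d_bwd_cpp")]]
List conv1d_bwd_cpp(const arma::mat& G, const arma::mat& W,
                    const arma::mat& M, int B, int L, int C, int k) {
  arma::mat dW = M.t() * G;
  arma::vec db = arma::sum(G, 0).t();
  arma::vec dx = col2im1d_cpp(G * W.t(), B, L, C, k);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// [[Rcpp::export(name = ".conv2d_fwd_cpp")]]
List conv2d_fwd_cpp(const arma::vec& x, int B, int H, int W0, int C,
                    const arma::mat& W, const arma::vec& b, int k) {
  arma::mat M = im2col2d_cpp(x, B, H, W0, C, k);
  arma::mat out = M * W;
  out.each_row() += b.t();
  return List::create(_["out"] = out, _["M"] = M);
}

// [[Rcpp::export(name = ".conv2d_bwd_cpp")]]
List conv2d_bwd_cpp(const arma::mat& G, const arma::mat& W,
                    const arma::mat& M, int B, int H, int W0, int C, int k) {
  arma::mat dW = M.t() * G;
  arma::vec db = arma::sum(G, 0).t();
  arma::vec dx = col2im2d_cpp(G * W.t(), B, H, W0, C, k);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// ---- batch normalization --------------------------------------------------

// Forward pass over the (N, C) channel-major view. In training mode the
// batch mean/variance are computed here and returned so the caller can
// update running statistics; otherwise the supplied running moments are
// used.
// [[Rcpp::export(name = ".bn_fwd_cpp")]]
List bn_fwd_cpp(const arma::vec& x, int N, int C, const arma::vec& gamma,
                const arma::vec& beta, const arma::vec& run_mean,
                const arma::vec& run_var, bool train, double eps) {
  arma::vec out((size_t)N * C), xhat((size_t)N * C), mu(C), va(C), ivar(C);
  for (int c = 0; c < C; ++c) {
    const double* s = x.memptr() + (size_t)N * c;
    double m, v;
    if (train) {
      double s1 = 0, s2 = 0;
      for (int r = 0; r < N; ++r) { s1 += s[r]; s2 += s[r] * s[r]; }
      m = s1 / N;
      v = s2 / N - m * m;
      if (v < 0) v = 0;
    } else {
      m = run_mean[c]; v = run_var[c];
    }
    mu[c] = m; va[c] = v;
    double iv = 1.0 / std::sqrt(v + eps);
    ivar[c] = iv;
    const double g = gamma[c], be = beta[c];
    double* xh = xhat.memptr() + (size_t)N * c;
    double* o = out.memptr() + (size_t)N * c;
    for (int r = 0; r < N; ++r) {
      xh[r] = (s[r] - m) * iv;
      o[r] = g * xh[r] + be;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mu"] = mu,
                      _["va"] = va, _["ivar"] = ivar);
}

// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(const arma::vec& dy_all, const arma::vec& xhat_all, int N,
                int C, const arma::vec& gamma, const arma::vec& ivar,
                bool train) {
  arma::vec dgamma(C), dbeta(C), dX((size_t)N * C);
  for (int c = 0; c < C; ++c) {
    const double* dy = dy_all.memptr() + (size_t)N * c;
    const double* xh = xhat_all.memptr() + (size_t)N * c;
    double sdy = 0, sdyx = 0;
    for (int r = 0; r < N; ++r) { sdy += dy[r]; sdyx += dy[r] * xh[r]; }
    dgamma[c] = sdyx; dbeta[c] = sdy;
    double g = gamma[c] * ivar[c];
    double* dx = dX.memptr() + (size_t)N * c;
    if (train) {
      double mdy = sdy / N, mdyx = sdyx / N;
      for (int r = 0; r < N; ++r) dx[r] = g * (dy[r] - mdy - xh[r] * mdyx);
    } else {
      for (int r = 0; r < N; ++r) dx[r] = g * dy[r];
    }
  }
  return List::create(_["dx"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
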
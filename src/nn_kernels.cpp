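// Dense 3D convolution and max-pooling kernels for the brain-age network.
// Layout conventions (all column-major, matching R arrays):
//   activations: dim (D, H, W, C, N), voxel index fastest
//   conv weights: matrix (K x Cout) with K = k^3 * Cin ordered
//                 (kd, kh, kw, cin), kd fastest -- i.e. matrix(w_array) for an
//                 R array of dim (k, k, k, Cin, Cout)
// "Same" padding with stride 1: pad_lo = (k - 1) / 2, pad_hi = k - 1 - pad_lo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill the im2col matrix (V x K) for one sample. x points at the sample's
// (D, H, W, Cin) block. V = D*H*W output voxels (same padding, stride 1).
static void im2col_t(const double* x, int D, int H, int W, int Cin, int k,
                     int pad_lo, arma::mat& colT) {
  const int V = D * H * W;
  colT.zeros();
  double* out = colT.memptr();
  int col = 0;  // column index = (kd, kh, kw, cin) with kd fastest
  for (int cin = 0; cin < Cin; ++cin) {
    const double* xc = x + (std::size_t)cin * V;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        for (int kd = 0; kd < k; ++kd, ++col) {
          double* dst = out + (std::size_t)col * V;
          const int dw = kw - pad_lo, dh = kh - pad_lo, dd = kd - pad_lo;
          const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const int d0 = std::max(0, -dd), d1 = std::min(D, D - dd);
          if (d1 <= d0) continue;
          for (int w = w0; w < w1; ++w) {
            for (int h = h0; h < h1; ++h) {
              const double* src =
                  xc + ((std::size_t)(w + dw) * H + (h + dh)) * D + (d0 + dd);
              double* d_out = dst + ((std::size_t)w * H + h) * D + d0;
              std::copy(src, src + (d1 - d0), d_out);
            }
          }
        }
      }
    }
  }
}

// Scatter-add the transpose of im2col back into an input-shaped gradient.
static void col2im_t(const arma::mat& colT, int D, int H, int W, int Cin,
                     int k, int pad_lo, double* gx) {
  const int V = D * H * W;
  const double* in = colT.memptr();
  int col = 0;
  for (int cin = 0; cin < Cin; ++cin) {
    double* gc = gx + (std::size_t)cin * V;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        for (int kd = 0; kd < k; ++kd, ++col) {
          const double* src0 = in + (std::size_t)col * V;
          const int dw = kw - pad_lo, dh = kh - pad_lo, dd = kd - pad_lo;
          const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const int d0 = std::max(0, -dd), d1 = std::min(D, D - dd);
          if (d1 <= d0) continue;
          for (int w = w0; w < w1; ++w) {
            for (int h = h0; h < h1; ++h) {
              double* dst =
                  gc + ((std::size_t)(w + dw) * H + (h + dh)) * D + (d0 + dd);
              const double* src = src0 + ((std::size_t)w * H + h) * D + d0;
              for (int d = 0; d < d1 - d0; ++d) dst[d] += src[d];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dims,
                             const arma::mat& wt, const arma::vec& bias,
                             int k, int pad_lo) {
  const int D = dims[0], H = dims[1], W = dims[2], Cin = dims[3], N = dims[4];
  const int V = D * H * W;
  const int K = k * k * k * Cin;
  const int Cout = wt.n_cols;
  if ((int)wt.n_rows != K) stop("weight matrix rows != k^3 * Cin");
  NumericVector out(Rcpp::no_init((std::size_t)V * Cout * N));
  out.attr("dim") = IntegerVector::create(D, H, W, Cout, N);
  arma::mat colT(V, K);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (std::size_t)n * V * Cin, D, H, W, Cin, k, pad_lo,
             colT);
    arma::mat o(out.begin() + (std::size_t)n * V * Cout, V, Cout, false, true);
    o = colT * wt;
    o.each_row() += bias.t();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dims, NumericVector gout,
                    const arma::mat& wt, int k, int pad_lo,
                    bool need_input_grad, bool need_weight_grad) {
  const int D = dims[0], H = dims[1], W = dims[2], Cin = dims[3], N = dims[4];
  const int V = D * H * W;
  const int K = k * k * k * Cin;
  const int Cout = wt.n_cols;
  NumericVector gx;
  if (need_input_grad) {
    gx = NumericVector((std::size_t)V * Cin * N);  // zero-initialized
    gx.attr("dim") = IntegerVector::create(D, H, W, Cin, N);
  }
  arma::mat gwt(K, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat colT;
  if (need_weight_grad) colT.set_size(V, K);
  arma::mat gcolT;
  if (need_input_grad) gcolT.set_size(V, K);
  for (int n = 0; n < N; ++n) {
    arma::mat go(gout.begin() + (std::size_t)n * V * Cout, V, Cout, false,
                 true);
    if (need_weight_grad) {
      im2col_t(x.begin() + (std::size_t)n * V * Cin, D, H, W, Cin, k, pad_lo,
               colT);
      gwt += colT.t() * go;
      gb += arma::sum(go, 0).t();
    }
    if (need_input_grad) {
      gcolT = go * wt.t();
      col2im_t(gcolT, D, H, W, Cin, k, pad_lo,
               gx.begin() + (std::size_t)n * V * Cin);
    }
  }
  return List::create(Named("gx") = gx, Named("gw") = gwt, Named("gb") = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector dims, int k) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3], N = dims[4];
  if (D % k || H % k || W % k) stop("pool kernel does not divide the grid");
  const int Do = D / k, Ho = H / k, Wo = W / k;
  const std::size_t Vi = (std::size_t)D * H * W;
  const std::size_t Vo = (std::size_t)Do * Ho * Wo;
  NumericVector out(Rcpp::no_init(Vo * C * N));
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, N);
  IntegerVector arg(Rcpp::no_init(Vo * C * N));  // 1-based within-sample index
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n) {
    const double* xs = xp + n * Vi * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xs + c * Vi;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          for (int d_o = 0; d_o < Do; ++d_o) {
            double best = -std::numeric_limits<double>::infinity();
            std::size_t best_i = 0;
            for (int kw = 0; kw < k; ++kw) {
              for (int kh = 0; kh < k; ++kh) {
                for (int kd = 0; kd < k; ++kd) {
                  std::size_t i =
                      ((std::size_t)(wo * k + kw) * H + (ho * k + kh)) * D +
                      (d_o * k + kd);
                  if (xc[i] > best) { best = xc[i]; best_i = i; }
                }
              }
            }
            std::size_t oi =
                (((std::size_t)n * C + c) * Wo + wo) * Ho * Do +
                (std::size_t)ho * Do + d_o;
            op[oi] = best;
            ap[oi] = (int)(c * Vi + best_i) + 1;
          }
        }
      }
    }
  }
  return List::create(Named("out") = out, Named("argmax") = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gout, IntegerVector argmax,
                              IntegerVector in_dims) {
  const int D = in_dims[0], H = in_dims[1], W = in_dims[2], C = in_dims[3],
            N = in_dims[4];
  const std::size_t Vi = (std::size_t)D * H * W;
  NumericVector gx((std::size_t)Vi * C * N);
  gx.attr("dim") = in_dims;
  const std::size_t per_sample = gout.size() / N;
  for (int n = 0; n < N; ++n) {
    double* gs = gx.begin() + n * Vi * C;
    const double* go = gout.begin() + n * per_sample;
    const int* am = argmax.begin() + n * per_sample;
    for (std::size_t i = 0; i < per_sample; ++i) gs[am[i] - 1] += go[i];
  }
  return gx;
}
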
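// Float32 compute kernels of the network engine.
//
// Activations travel between R and C++ as raw vectors holding IEEE float32,
// one column per channel, rows ordered row-major over (batch, row, col):
// row = (b*H + r)*W + c (0-based). Master weights stay double on the R
// side (Adam runs in double); each kernel converts the small weight arrays
// on entry and returns double gradients. Spatial convolutions are direct
// register-blocked loops (much faster than im2col+GEMM at these channel
// widths); 1x1 convolutions and transposed convolutions go through sgemm.
// All reductions (batch-norm statistics, weight gradients) accumulate in
// double. Single-threaded and sequenced, so results are bit-reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cfloat>
using namespace Rcpp;

static inline float* FP(RawVector& x) {
  return reinterpret_cast<float*>(RAW(x));
}
static inline const float* FP(const RawVector& x) {
  return reinterpret_cast<const float*>(RAW(x));
}
static RawVector falloc(R_xlen_t n) { return RawVector(4 * n); }

// ---- conversions -----------------------------------------------------------

// [[Rcpp::export]]
RawVector f_d2f(const NumericVector& x) {
  RawVector out = falloc(x.size());
  float* o = FP(out);
  for (R_xlen_t i = 0; i < x.size(); ++i) o[i] = (float)x[i];
  return out;
}

// [[Rcpp::export]]
NumericVector f_f2d(const RawVector& x) {
  R_xlen_t n = x.size() / 4;
  NumericVector out(n);
  const float* p = FP(x);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = p[i];
  return out;
}

// Sigmoid to double probabilities (the loss side runs in double).
// [[Rcpp::export]]
NumericVector f_sigmoid(const RawVector& x) {
  R_xlen_t n = x.size() / 4;
  NumericVector out(n);
  const float* p = FP(x);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-(double)p[i]));
  return out;
}

// In-place accumulation a += b for gradient fan-in.
// [[Rcpp::export]]
void f_add_inplace(RawVector& a, const RawVector& b) {
  R_xlen_t n = a.size() / 4;
  float* pa = FP(a);
  const float* pb = FP(b);
  for (R_xlen_t i = 0; i < n; ++i) pa[i] += pb[i];
}

// ---- GEMM paths (1x1 convolution etc.) ------------------------------------

static arma::fmat wrapF(const RawVector& x, int nr, int nc) {
  return arma::fmat(const_cast<float*>(FP(x)), nr, nc, false, true);
}

static NumericMatrix toDouble(const arma::fmat& A) {
  NumericMatrix out(A.n_rows, A.n_cols);
  for (arma::uword j = 0; j < A.n_cols; ++j)
    for (arma::uword i = 0; i < A.n_rows; ++i) out(i, j) = A(i, j);
  return out;
}

static arma::fmat toFloat(const NumericMatrix& A) {
  arma::fmat F(A.nrow(), A.ncol());
  for (int j = 0; j < A.ncol(); ++j)
    for (int i = 0; i < A.nrow(); ++i) F(i, j) = (float)A(i, j);
  return F;
}

// Y = X * W (+ bias); X raw float (N x Cin), W double (Cin x Cout).
// [[Rcpp::export]]
RawVector f_gemm_fwd(const RawVector& X, int N, int Cin,
                     const NumericMatrix& W, const NumericVector& bias) {
  arma::fmat Xf = wrapF(X, N, Cin);
  arma::fmat Wf = toFloat(W);
  RawVector out = falloc((R_xlen_t)N * Wf.n_cols);
  arma::fmat Y(FP(out), N, Wf.n_cols, false, true);
  Y = Xf * Wf;
  if (bias.size() > 0)
    for (arma::uword j = 0; j < Y.n_cols; ++j) Y.col(j) += (float)bias[j];
  return out;
}

// dX = G * t(W)
// [[Rcpp::export]]
RawVector f_gemm_dx(const RawVector& G, int N, int Cout,
                    const NumericMatrix& W) {
  arma::fmat Gf = wrapF(G, N, Cout);
  arma::fmat Wf = toFloat(W);
  RawVector out = falloc((R_xlen_t)N * Wf.n_rows);
  arma::fmat dX(FP(out), N, Wf.n_rows, false, true);
  dX = Gf * Wf.t();
  return out;
}

// dW = t(X) * G, returned in double.
// [[Rcpp::export]]
NumericMatrix f_gemm_dw(const RawVector& X, int N, int Cin,
                        const RawVector& G, int Cout) {
  arma::fmat Xf = wrapF(X, N, Cin);
  arma::fmat Gf = wrapF(G, N, Cout);
  arma::fmat dW = Xf.t() * Gf;
  return toDouble(dW);
}

// [[Rcpp::export]]
NumericVector f_colsum(const RawVector& G, int N, int C) {
  NumericVector out(C);
  const float* g = FP(G);
  for (int ch = 0; ch < C; ++ch) {
    const float* gs = g + (size_t)ch * N;
    double s = 0;
    for (int i = 0; i < N; ++i) s += gs[i];
    out[ch] = s;
  }
  return out;
}

// ---- spatial convolution -----------------------------------------------
//
// Two routes, chosen by the R side: direct row-buffered loops (fast when
// the spatial extent is large and channels few -- the shallow levels), and
// im2col + sgemm (fast when channels are many and the canvas small -- the
// deep levels). Weight layout everywhere: (Cin*kh*kw) x Cout with one
// Cin-row block per kernel offset, offsets ordered row-major.

// Direct forward: one pass over the input; a (W x Cout) row accumulator
// keeps all traffic cache-resident, vectorized over output channels.
// [[Rcpp::export]]
RawVector f_conv_fwd(const RawVector& X, int H, int W, int B, int Cin,
                     const NumericMatrix& Wt, int kh, int kw) {
  const int Cout = Wt.ncol();
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const size_t N = (size_t)H * W * B;
  // wf[(blk*Cin + ci)*Cout + co]: output channel contiguous
  std::vector<float> wf((size_t)Wt.nrow() * Cout);
  for (int i = 0; i < Wt.nrow(); ++i)
    for (int co = 0; co < Cout; ++co)
      wf[(size_t)i * Cout + co] = (float)Wt(i, co);
  RawVector out = falloc((R_xlen_t)(N * Cout));
  float* y = FP(out);
  const float* x = FP(X);
  std::vector<float> buf((size_t)W * Cout);
  for (int b = 0; b < B; ++b)
    for (int r = 0; r < H; ++r) {
      std::fill(buf.begin(), buf.end(), 0.0f);
      for (int di = -ph; di <= ph; ++di) {
        int sr = r + di;
        if (sr < 0 || sr >= H) continue;
        for (int ci = 0; ci < Cin; ++ci) {
          const float* xrow = x + (size_t)ci * N + ((size_t)(b * H + sr)) * W;
          for (int dj = -pw; dj <= pw; ++dj) {
            int blk = (di + ph) * kw + (dj + pw);
            const float* wp = wf.data() + ((size_t)blk * Cin + ci) * Cout;
            int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
            for (int c = c0; c < c1; ++c) {
              const float xv = xrow[c + dj];
              float* bp = buf.data() + (size_t)c * Cout;
              for (int co = 0; co < Cout; ++co) bp[co] += wp[co] * xv;
            }
          }
        }
      }
      for (int co = 0; co < Cout; ++co) {
        float* yrow = y + (size_t)co * N + ((size_t)(b * H + r)) * W;
        const float* bp = buf.data() + co;
        for (int c = 0; c < W; ++c) yrow[c] = bp[(size_t)c * Cout];
      }
    }
  return out;
}

// Direct input gradient: correlation with the flipped kernel, same row
// buffering, vectorized over input channels.
// [[Rcpp::export]]
RawVector f_conv_dx(const RawVector& G, int H, int W, int B, int Cin,
                    const NumericMatrix& Wt, int kh, int kw) {
  const int Cout = Wt.ncol();
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const size_t N = (size_t)H * W * B;
  // wt2[(blk*Cout + co)*Cin + ci]: input channel contiguous
  std::vector<float> wt2((size_t)Wt.nrow() * Cout);
  for (int blk = 0; blk < kh * kw; ++blk)
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < Cout; ++co)
        wt2[((size_t)blk * Cout + co) * Cin + ci] =
          (float)Wt(blk * Cin + ci, co);
  RawVector out = falloc((R_xlen_t)(N * Cin));
  float* dx = FP(out);
  const float* g = FP(G);
  std::vector<float> buf((size_t)W * Cin);
  for (int b = 0; b < B; ++b)
    for (int r = 0; r < H; ++r) {
      std::fill(buf.begin(), buf.end(), 0.0f);
      for (int di = -ph; di <= ph; ++di) {
        int gr = r - di;
        if (gr < 0 || gr >= H) continue;
        for (int co = 0; co < Cout; ++co) {
          const float* grow = g + (size_t)co * N + ((size_t)(b * H + gr)) * W;
          for (int dj = -pw; dj <= pw; ++dj) {
            int blk = (di + ph) * kw + (dj + pw);
            const float* wp = wt2.data() + ((size_t)blk * Cout + co) * Cin;
            int c0 = std::max(0, dj), c1 = std::min(W, W + dj);
            for (int c = c0; c < c1; ++c) {
              const float gv = grow[c - dj];
              float* bp = buf.data() + (size_t)c * Cin;
              for (int ci = 0; ci < Cin; ++ci) bp[ci] += wp[ci] * gv;
            }
          }
        }
      }
      for (int ci = 0; ci < Cin; ++ci) {
        float* drow = dx + (size_t)ci * N + ((size_t)(b * H + r)) * W;
        const float* bp = buf.data() + ci;
        for (int c = 0; c < W; ++c) drow[c] = bp[(size_t)c * Cin];
      }
    }
  return out;
}

// Direct weight gradient: single streaming pass with double accumulators;
// the output-channel gradient rows are transposed into a cache-resident
// row buffer first.
// [[Rcpp::export]]
NumericMatrix f_conv_dw(const RawVector& X, const RawVector& G,
                        int H, int W, int B, int Cin, int Cout,
                        int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const size_t N = (size_t)H * W * B;
  std::vector<double> acc((size_t)kh * kw * Cin * Cout, 0.0);
  const float* x = FP(X);
  const float* g = FP(G);
  std::vector<float> gbuf((size_t)W * Cout);
  for (int b = 0; b < B; ++b)
    for (int r = 0; r < H; ++r) {
      for (int co = 0; co < Cout; ++co) {
        const float* grow = g + (size_t)co * N + ((size_t)(b * H + r)) * W;
        float* bp = gbuf.data() + co;
        for (int c = 0; c < W; ++c) bp[(size_t)c * Cout] = grow[c];
      }
      for (int di = -ph; di <= ph; ++di) {
        int sr = r + di;
        if (sr < 0 || sr >= H) continue;
        for (int ci = 0; ci < Cin; ++ci) {
          const float* xrow = x + (size_t)ci * N + ((size_t)(b * H + sr)) * W;
          for (int dj = -pw; dj <= pw; ++dj) {
            int blk = (di + ph) * kw + (dj + pw);
            double* ap = acc.data() + ((size_t)blk * Cin + ci) * Cout;
            int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
            for (int c = c0; c < c1; ++c) {
              const float xv = xrow[c + dj];
              const float* bp = gbuf.data() + (size_t)c * Cout;
              for (int co = 0; co < Cout; ++co) ap[co] += (double)xv * bp[co];
            }
          }
        }
      }
    }
  NumericMatrix dW(Cin * kh * kw, Cout);
  for (int i = 0; i < Cin * kh * kw; ++i)
    for (int co = 0; co < Cout; ++co)
      dW(i, co) = acc[(size_t)i * Cout + co];
  return dW;
}

// Float im2col / col2im for the sgemm route at the deep levels.
// Column block for offset o holds the input shifted by (di, dj).
// [[Rcpp::export]]
RawVector f_im2col(const RawVector& X, int H, int W, int B, int Cin,
                   int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const size_t N = (size_t)H * W * B;
  RawVector out = falloc((R_xlen_t)(N * Cin * kh * kw));
  float* o = FP(out);
  const float* x = FP(X);
  int blk = 0;
  for (int di = -ph; di <= ph; ++di)
    for (int dj = -pw; dj <= pw; ++dj, ++blk)
      for (int ch = 0; ch < Cin; ++ch) {
        const float* xs = x + (size_t)ch * N;
        float* os = o + (size_t)(blk * Cin + ch) * N;
        for (int b = 0; b < B; ++b)
          for (int r = 0; r < H; ++r) {
            int sr = r + di;
            float* orow = os + ((size_t)(b * H + r)) * W;
            if (sr < 0 || sr >= H) {
              std::fill(orow, orow + W, 0.0f);
              continue;
            }
            const float* xrow = xs + ((size_t)(b * H + sr)) * W;
            int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
            for (int c = 0; c < c0; ++c) orow[c] = 0.0f;
            for (int c = c0; c < c1; ++c) orow[c] = xrow[c + dj];
            for (int c = c1; c < W; ++c) orow[c] = 0.0f;
          }
      }
  return out;
}

// [[Rcpp::export]]
RawVector f_col2im(const RawVector& Gcol, int H, int W, int B, int Cin,
                   int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const size_t N = (size_t)H * W * B;
  RawVector out = falloc((R_xlen_t)(N * Cin));
  float* o = FP(out);
  std::fill(o, o + N * Cin, 0.0f);
  const float* g = FP(Gcol);
  int blk = 0;
  for (int di = -ph; di <= ph; ++di)
    for (int dj = -pw; dj <= pw; ++dj, ++blk)
      for (int ch = 0; ch < Cin; ++ch) {
        const float* gs = g + (size_t)(blk * Cin + ch) * N;
        float* os = o + (size_t)ch * N;
        for (int b = 0; b < B; ++b)
          for (int r = 0; r < H; ++r) {
            int sr = r + di;
            if (sr < 0 || sr >= H) continue;
            const float* grow = gs + ((size_t)(b * H + r)) * W;
            float* orow = os + ((size_t)(b * H + sr)) * W;
            int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
            for (int c = c0; c < c1; ++c) orow[c + dj] += grow[c];
          }
      }
  return out;
}

// ---- fused batch-norm + ReLU ----------------------------------------------

// Training mode: batch moments (double accumulation), normalize, scale,
// shift, clamp at zero. Only y and the per-channel moments are returned;
// backward recomputes xhat from the (already-retained) input.
// [[Rcpp::export]]
List f_bnrelu_train(const RawVector& X, int N, int C,
                    const NumericVector& gamma, const NumericVector& beta,
                    double eps) {
  RawVector yv = falloc((R_xlen_t)N * C);
  NumericVector mu(C), var(C), invstd(C);
  const float* x = FP(X);
  float* y = FP(yv);
  for (int ch = 0; ch < C; ++ch) {
    const float* xs = x + (size_t)ch * N;
    double s = 0, s2 = 0;
    for (int i = 0; i < N; ++i) { s += xs[i]; s2 += (double)xs[i] * xs[i]; }
    double m = s / N, v = s2 / N - m * m;
    if (v < 0) v = 0;
    mu[ch] = m; var[ch] = v;
    double is = 1.0 / std::sqrt(v + eps);
    invstd[ch] = is;
    const float a = (float)(gamma[ch] * is);
    const float b = (float)(beta[ch] - gamma[ch] * is * m);
    float* ys = y + (size_t)ch * N;
    for (int i = 0; i < N; ++i) {
      float o = a * xs[i] + b;
      ys[i] = o > 0.0f ? o : 0.0f;
    }
  }
  return List::create(_["y"] = yv, _["mu"] = mu, _["var"] = var,
                      _["invstd"] = invstd);
}

// Inference mode: running moments.
// [[Rcpp::export]]
RawVector f_bnrelu_eval(const RawVector& X, int N, int C,
                        const NumericVector& gamma,
                        const NumericVector& beta,
                        const NumericVector& rm, const NumericVector& rv,
                        double eps) {
  RawVector yv = falloc((R_xlen_t)N * C);
  const float* x = FP(X);
  float* y = FP(yv);
  for (int ch = 0; ch < C; ++ch) {
    double is = 1.0 / std::sqrt(rv[ch] + eps);
    const float a = (float)(gamma[ch] * is);
    const float b = (float)(beta[ch] - gamma[ch] * is * rm[ch]);
    const float* xs = x + (size_t)ch * N;
    float* ys = y + (size_t)ch * N;
    for (int i = 0; i < N; ++i) {
      float o = a * xs[i] + b;
      ys[i] = o > 0.0f ? o : 0.0f;
    }
  }
  return yv;
}

// Fused backward through ReLU then batch norm (training moments). The
// ReLU mask comes from y > 0; xhat is recomputed from x, mu and invstd.
// [[Rcpp::export]]
List f_bnrelu_bwd(const RawVector& G, const RawVector& X,
                  const RawVector& Y, int N, int C,
                  const NumericVector& gamma, const NumericVector& mu,
                  const NumericVector& invstd) {
  RawVector dxv = falloc((R_xlen_t)N * C);
  NumericVector dgamma(C), dbeta(C);
  const float* g = FP(G);
  const float* x = FP(X);
  const float* y = FP(Y);
  float* dx = FP(dxv);
  for (int ch = 0; ch < C; ++ch) {
    const float* gs = g + (size_t)ch * N;
    const float* xs = x + (size_t)ch * N;
    const float* ys = y + (size_t)ch * N;
    const float mf = (float)mu[ch], is = (float)invstd[ch];
    double sg = 0, sb = 0;
    for (int i = 0; i < N; ++i) {
      if (ys[i] > 0.0f) {
        sg += (double)gs[i] * ((xs[i] - mf) * is);
        sb += gs[i];
      }
    }
    dgamma[ch] = sg; dbeta[ch] = sb;
    const float gm = (float)gamma[ch];
    const float c1 = (float)(sb * gamma[ch] / N);
    const float c2 = (float)(sg * gamma[ch] / N);
    float* ds = dx + (size_t)ch * N;
    for (int i = 0; i < N; ++i) {
      float gr = ys[i] > 0.0f ? gs[i] : 0.0f;
      float xh = (xs[i] - mf) * is;
      ds[i] = is * (gr * gm - c1 - xh * c2);
    }
  }
  return List::create(_["dx"] = dxv, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- pooling ---------------------------------------------------------------

// 2x2 max pooling, stride 2; winner index (1..4) per output element.
// [[Rcpp::export]]
List f_maxpool2(const RawVector& X, int H, int W, int B, int C) {
  const int Ho = H / 2, Wo = W / 2;
  const size_t N = (size_t)H * W * B, No = (size_t)Ho * Wo * B;
  RawVector yv = falloc((R_xlen_t)(No * C));
  RawVector whv((R_xlen_t)(No * C));
  const float* x = FP(X);
  float* y = FP(yv);
  unsigned char* wh = RAW(whv);
  for (int ch = 0; ch < C; ++ch) {
    const float* xs = x + (size_t)ch * N;
    float* ys = y + (size_t)ch * No;
    unsigned char* ws = wh + (size_t)ch * No;
    for (int b = 0; b < B; ++b)
      for (int r = 0; r < Ho; ++r) {
        const float* row0 = xs + ((size_t)(b * H + 2 * r)) * W;
        const float* row1 = row0 + W;
        float* yrow = ys + ((size_t)(b * Ho + r)) * Wo;
        unsigned char* wrow = ws + ((size_t)(b * Ho + r)) * Wo;
        for (int c = 0; c < Wo; ++c) {
          float m = row0[2 * c]; unsigned char k = 1;
          if (row0[2 * c + 1] > m) { m = row0[2 * c + 1]; k = 2; }
          if (row1[2 * c] > m) { m = row1[2 * c]; k = 3; }
          if (row1[2 * c + 1] > m) { m = row1[2 * c + 1]; k = 4; }
          yrow[c] = m; wrow[c] = k;
        }
      }
  }
  return List::create(_["y"] = yv, _["wh"] = whv);
}

// [[Rcpp::export]]
RawVector f_maxpool2_bwd(const RawVector& G, const RawVector& wh,
                         int H, int W, int B, int C) {
  const int Ho = H / 2, Wo = W / 2;
  const size_t N = (size_t)H * W * B, No = (size_t)Ho * Wo * B;
  RawVector dxv = falloc((R_xlen_t)(N * C));
  float* dx = FP(dxv);
  std::fill(dx, dx + N * C, 0.0f);
  const float* g = FP(G);
  const unsigned char* w = RAW(wh);
  for (int ch = 0; ch < C; ++ch) {
    const float* gs = g + (size_t)ch * No;
    const unsigned char* ws = w + (size_t)ch * No;
    float* ds = dx + (size_t)ch * N;
    for (int b = 0; b < B; ++b)
      for (int r = 0; r < Ho; ++r) {
        const float* grow = gs + ((size_t)(b * Ho + r)) * Wo;
        const unsigned char* wrow = ws + ((size_t)(b * Ho + r)) * Wo;
        float* row0 = ds + ((size_t)(b * H + 2 * r)) * W;
        float* row1 = row0 + W;
        for (int c = 0; c < Wo; ++c) {
          switch (wrow[c]) {
            case 1: row0[2 * c] += grow[c]; break;
            case 2: row0[2 * c + 1] += grow[c]; break;
            case 3: row1[2 * c] += grow[c]; break;
            default: row1[2 * c + 1] += grow[c];
          }
        }
      }
  }
  return dxv;
}

// 3x3 max pooling, stride 1, same padding, computed separably: a 1x3 row
// max with argument, then a 3x1 column max over it. The winner offset is
// stored as 3*(di+1) + (dj+1) + 1 in 1..9 (first maximum in row-major
// scan order wins ties, as in a direct 9-way scan). Interior columns run
// branch-free so the compiler can vectorize.
// [[Rcpp::export]]
List f_maxpool3(const RawVector& X, int H, int W, int B, int C) {
  const size_t N = (size_t)H * W * B;
  RawVector yv = falloc((R_xlen_t)(N * C));
  RawVector whv((R_xlen_t)(N * C));
  std::vector<float> rowmax(N);
  std::vector<signed char> rowarg(N);
  const float* x = FP(X);
  float* y = FP(yv);
  unsigned char* wh = RAW(whv);
  for (int ch = 0; ch < C; ++ch) {
    const float* xs = x + (size_t)ch * N;
    // horizontal pass: max over dj in {-1,0,1}; ties -> smaller dj
    for (int b = 0; b < B; ++b)
      for (int r = 0; r < H; ++r) {
        const float* xr = xs + ((size_t)(b * H + r)) * W;
        float* mr = rowmax.data() + ((size_t)(b * H + r)) * W;
        signed char* ar = rowarg.data() + ((size_t)(b * H + r)) * W;
        for (int c = 1; c < W - 1; ++c) {
          float m = xr[c - 1]; signed char k = -1;
          if (xr[c] > m) { m = xr[c]; k = 0; }
          if (xr[c + 1] > m) { m = xr[c + 1]; k = 1; }
          mr[c] = m; ar[c] = k;
        }
        { // c = 0
          float m = xr[0]; signed char k = 0;
          if (W > 1 && xr[1] > m) { m = xr[1]; k = 1; }
          mr[0] = m; ar[0] = k;
        }
        if (W > 1) { // c = W-1
          float m = xr[W - 2]; signed char k = -1;
          if (xr[W - 1] > m) { m = xr[W - 1]; k = 0; }
          mr[W - 1] = m; ar[W - 1] = k;
        }
      }
    // vertical pass: max over di in {-1,0,1}; ties -> smaller di
    float* ys = y + (size_t)ch * N;
    unsigned char* ws = wh + (size_t)ch * N;
    for (int b = 0; b < B; ++b)
      for (int r = 0; r < H; ++r) {
        float* yr = ys + ((size_t)(b * H + r)) * W;
        unsigned char* wr = ws + ((size_t)(b * H + r)) * W;
        const float* m1 = rowmax.data() + ((size_t)(b * H + r)) * W;
        const signed char* a1 = rowarg.data() + ((size_t)(b * H + r)) * W;
        if (r > 0 && r + 1 < H) {
          const float* m0 = m1 - W;
          const float* m2 = m1 + W;
          const signed char* a0 = a1 - W;
          const signed char* a2 = a1 + W;
          for (int c = 0; c < W; ++c) {
            float m = m0[c]; int di = -1;
            if (m1[c] > m) { m = m1[c]; di = 0; }
            if (m2[c] > m) { m = m2[c]; di = 1; }
            const signed char* aa = di < 0 ? a0 : (di == 0 ? a1 : a2);
            yr[c] = m;
            wr[c] = (unsigned char)(3 * (di + 1) + (aa[c] + 1) + 1);
          }
        } else {
          const float* m0 = r > 0 ? m1 - W : NULL;
          const float* m2 = r + 1 < H ? m1 + W : NULL;
          const signed char* a0 = r > 0 ? a1 - W : NULL;
          const signed char* a2 = r + 1 < H ? a1 + W : NULL;
          for (int c = 0; c < W; ++c) {
            float m; int di;
            if (m0 && m0[c] >= m1[c]) { m = m0[c]; di = -1; }
            else { m = m1[c]; di = 0; }
            if (m2 && m2[c] > m) { m = m2[c]; di = 1; }
            const signed char* aa = di < 0 ? a0 : (di == 0 ? a1 : a2);
            yr[c] = m;
            wr[c] = (unsigned char)(3 * (di + 1) + (aa[c] + 1) + 1);
          }
        }
      }
  }
  return List::create(_["y"] = yv, _["wh"] = whv);
}

// [[Rcpp::export]]
RawVector f_maxpool3_bwd(const RawVector& G, const RawVector& wh,
                         int H, int W, int B, int C) {
  const size_t N = (size_t)H * W * B;
  RawVector dxv = falloc((R_xlen_t)(N * C));
  float* dx = FP(dxv);
  std::fill(dx, dx + N * C, 0.0f);
  const float* g = FP(G);
  const unsigned char* w = RAW(wh);
  for (int ch = 0; ch < C; ++ch) {
    const float* gs = g + (size_t)ch * N;
    const unsigned char* ws = w + (size_t)ch * N;
    float* ds = dx + (size_t)ch * N;
    for (int b = 0; b < B; ++b)
      for (int r = 0; r < H; ++r) {
        const float* grow = gs + ((size_t)(b * H + r)) * W;
        const unsigned char* wrow = ws + ((size_t)(b * H + r)) * W;
        for (int c = 0; c < W; ++c) {
          int k = wrow[c] - 1;
          int sr = r + k / 3 - 1, sc = c + k % 3 - 1;
          ds[((size_t)(b * H + sr)) * W + sc] += grow[c];
        }
      }
  }
  return dxv;
}

// ---- stride-2 upsampling ---------------------------------------------------

// Transposed 2x2 stride-2 convolution. Weight (Cin*4) x Cout blocked per
// output sub-position (di outer, dj inner); windows do not overlap.
// [[Rcpp::export]]
RawVector f_up2_fwd(const RawVector& X, int H, int W, int B, int Cin,
                    const NumericMatrix& Wt) {
  const int Cout = Wt.ncol();
  const size_t N = (size_t)H * W * B, No = 4 * N;
  arma::fmat Xf = wrapF(X, N, Cin);
  arma::fmat Wf = toFloat(Wt);
  RawVector out = falloc((R_xlen_t)(No * Cout));
  float* y = FP(out);
  const int H2 = 2 * H, W2 = 2 * W;
  int o = 0;
  for (int di = 0; di <= 1; ++di)
    for (int dj = 0; dj <= 1; ++dj, ++o) {
      arma::fmat Yo = Xf * Wf.rows(o * Cin, (o + 1) * Cin - 1);
      for (int co = 0; co < Cout; ++co) {
        const float* src = Yo.colptr(co);
        float* ys = y + (size_t)co * No;
        for (int b = 0; b < B; ++b)
          for (int r = 0; r < H; ++r) {
            const float* srow = src + ((size_t)(b * H + r)) * W;
            float* yrow = ys + ((size_t)(b * H2 + 2 * r + di)) * W2 + dj;
            for (int c = 0; c < W; ++c) yrow[2 * c] = srow[c];
          }
      }
    }
  return out;
}

// [[Rcpp::export]]
List f_up2_bwd(const RawVector& X, const RawVector& G, int H, int W, int B,
               int Cin, const NumericMatrix& Wt) {
  const int Cout = Wt.ncol();
  const size_t N = (size_t)H * W * B, No = 4 * N;
  arma::fmat Xf = wrapF(X, N, Cin);
  arma::fmat Wf = toFloat(Wt);
  const float* g = FP(G);
  const int H2 = 2 * H, W2 = 2 * W;
  RawVector dxv = falloc((R_xlen_t)(N * Cin));
  arma::fmat dX(FP(dxv), N, Cin, false, true);
  dX.zeros();
  NumericMatrix dW(Wt.nrow(), Cout);
  arma::fmat Go(N, Cout);
  int o = 0;
  for (int di = 0; di <= 1; ++di)
    for (int dj = 0; dj <= 1; ++dj, ++o) {
      for (int co = 0; co < Cout; ++co) {
        float* dst = Go.colptr(co);
        const float* gs = g + (size_t)co * No;
        for (int b = 0; b < B; ++b)
          for (int r = 0; r < H; ++r) {
            float* drow = dst + ((size_t)(b * H + r)) * W;
            const float* grow = gs + ((size_t)(b * H2 + 2 * r + di)) * W2 + dj;
            for (int c = 0; c < W; ++c) drow[c] = grow[2 * c];
          }
      }
      arma::fmat blk = Wf.rows(o * Cin, (o + 1) * Cin - 1);
      dX += Go * blk.t();
      arma::fmat dWb = Xf.t() * Go;
      for (int j = 0; j < Cout; ++j)
        for (int i = 0; i < Cin; ++i) dW(o * Cin + i, j) = dWb(i, j);
    }
  return List::create(_["dx"] = dxv, _["dw"] = dW);
}

// Nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export]]
RawVector f_upnn_fwd(const RawVector& X, int H, int W, int B, int C) {
  const size_t N = (size_t)H * W * B, No = 4 * N;
  RawVector out = falloc((R_xlen_t)(No * C));
  float* y = FP(out);
  const float* x = FP(X);
  const int H2 = 2 * H, W2 = 2 * W;
  for (int ch = 0; ch < C; ++ch) {
    const float* xs = x + (size_t)ch * N;
    float* ys = y + (size_t)ch * No;
    for (int b = 0; b < B; ++b)
      for (int r = 0; r < H; ++r) {
        const float* xrow = xs + ((size_t)(b * H + r)) * W;
        float* y0 = ys + ((size_t)(b * H2 + 2 * r)) * W2;
        float* y1 = y0 + W2;
        for (int c = 0; c < W; ++c) {
          y0[2 * c] = xrow[c]; y0[2 * c + 1] = xrow[c];
          y1[2 * c] = xrow[c]; y1[2 * c + 1] = xrow[c];
        }
      }
  }
  return out;
}

// [[Rcpp::export]]
RawVector f_upnn_bwd(const RawVector& G, int H, int W, int B, int C) {
  const size_t N = (size_t)H * W * B, No = 4 * N;
  RawVector out = falloc((R_xlen_t)(N * C));
  float* dx = FP(out);
  const float* g = FP(G);
  const int H2 = 2 * H, W2 = 2 * W;
  for (int ch = 0; ch < C; ++ch) {
    float* ds = dx + (size_t)ch * N;
    const float* gs = g + (size_t)ch * No;
    for (int b = 0; b < B; ++b)
      for (int r = 0; r < H; ++r) {
        float* drow = ds + ((size_t)(b * H + r)) * W;
        const float* g0 = gs + ((size_t)(b * H2 + 2 * r)) * W2;
        const float* g1 = g0 + W2;
        for (int c = 0; c < W; ++c)
          drow[c] = g0[2 * c] + g0[2 * c + 1] + g1[2 * c] + g1[2 * c + 1];
      }
  }
  return out;
}

// ---- channel concatenation -------------------------------------------------

// [[Rcpp::export]]
RawVector f_concat2(const RawVector& A, int Ca, const RawVector& Bv,
                    int Cb, int N) {
  RawVector out = falloc((R_xlen_t)N * (Ca + Cb));
  std::memcpy(FP(out), FP(A), sizeof(float) * (size_t)N * Ca);
  std::memcpy(FP(out) + (size_t)N * Ca, FP(Bv),
              sizeof(float) * (size_t)N * Cb);
  return out;
}

// [[Rcpp::export]]
RawVector f_concat4(const RawVector& A, int Ca, const RawVector& Bv, int Cb,
                    const RawVector& Cv, int Cc, const RawVector& D, int Cd,
                    int N) {
  RawVector out = falloc((R_xlen_t)N * (Ca + Cb + Cc + Cd));
  float* o = FP(out);
  std::memcpy(o, FP(A), sizeof(float) * (size_t)N * Ca);
  o += (size_t)N * Ca;
  std::memcpy(o, FP(Bv), sizeof(float) * (size_t)N * Cb);
  o += (size_t)N * Cb;
  std::memcpy(o, FP(Cv), sizeof(float) * (size_t)N * Cc);
  o += (size_t)N * Cc;
  std::memcpy(o, FP(D), sizeof(float) * (size_t)N * Cd);
  return out;
}

// Extract a contiguous block of channels (concat backward).
// [[Rcpp::export]]
RawVector f_colslice(const RawVector& X, int N, int from, int nc) {
  RawVector out = falloc((R_xlen_t)N * nc);
  std::memcpy(FP(out), FP(X) + (size_t)N * (from - 1),
              sizeof(float) * (size_t)N * nc);
  return out;
}
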
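#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Feature maps are numeric vectors in (H, W, C, N) column-major layout:
// index = h + H*(w + W*(c + C*n)).

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// im2col: rows ordered (kh fastest, kw, c); columns ordered (ho fastest, wo, n).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int pad, int stride, int dil) {
  int Hout = (H + 2 * pad - dil * (kh - 1) - 1) / stride + 1;
  int Wout = (W + 2 * pad - dil * (kw - 1) - 1) / stride + 1;
  NumericMatrix col(kh * kw * C, Hout * Wout * N);
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wout; ++wo)
      for (int ho = 0; ho < Hout; ++ho) {
        int colj = ho + Hout * (wo + Wout * n);
        double* dst = &col(0, colj);
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < kw; ++j) {
            int wi = wo * stride - pad + j * dil;
            for (int i = 0; i < kh; ++i) {
              int hi = ho * stride - pad + i * dil;
              double v = 0.0;
              if (hi >= 0 && hi < H && wi >= 0 && wi < W)
                v = x[idx4(hi, wi, c, n, H, W, C)];
              dst[i + kh * (j + kw * c)] = v;
            }
          }
      }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix col, int H, int W, int C, int N,
                         int kh, int kw, int pad, int stride, int dil) {
  int Hout = (H + 2 * pad - dil * (kh - 1) - 1) / stride + 1;
  int Wout = (W + 2 * pad - dil * (kw - 1) - 1) / stride + 1;
  NumericVector x(H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wout; ++wo)
      for (int ho = 0; ho < Hout; ++ho) {
        int colj = ho + Hout * (wo + Wout * n);
        double* src = &col(0, colj);
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < kw; ++j) {
            int wi = wo * stride - pad + j * dil;
            for (int i = 0; i < kh; ++i) {
              int hi = ho * stride - pad + i * dil;
              if (hi >= 0 && hi < H && wi >= 0 && wi < W)
                x[idx4(hi, wi, c, n, H, W, C)] += src[i + kh * (j + kw * c)];
            }
          }
      }
  return x;
}

// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int C, int N,
                 int k, int stride, int pad) {
  int Hout = (H + 2 * pad - k) / stride + 1;
  int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector y(Hout * Wout * C * N);
  IntegerVector arg(Hout * Wout * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          double best = -DBL_MAX; int bi = -1;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              double v = x[idx4(hi, wi, c, n, H, W, C)];
              if (v > best) { best = v; bi = idx4(hi, wi, c, n, H, W, C); }
            }
          }
          int o = idx4(ho, wo, c, n, Hout, Wout, C);
          y[o] = (bi < 0) ? 0.0 : best;
          arg[o] = bi;
        }
  return List::create(_["y"] = y, _["arg"] = arg,
                      _["Hout"] = Hout, _["Wout"] = Wout);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_grad(NumericVector dy, IntegerVector arg, int len) {
  NumericVector dx(len);
  for (int i = 0; i < dy.size(); ++i)
    if (arg[i] >= 0) dx[arg[i]] += dy[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool(NumericVector x, int H, int W, int C, int N,
                          int k, int stride) {
  int Hout = (H - k) / stride + 1;
  int Wout = (W - k) / stride + 1;
  NumericVector y(Hout * Wout * C * N);
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          double s = 0.0;
          for (int j = 0; j < k; ++j)
            for (int i = 0; i < k; ++i)
              s += x[idx4(ho * stride + i, wo * stride + j, c, n, H, W, C)];
          y[idx4(ho, wo, c, n, Hout, Wout, C)] = s * inv;
        }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_grad(NumericVector dy, int H, int W, int C, int N,
                               int k, int stride) {
  int Hout = (H - k) / stride + 1;
  int Wout = (W - k) / stride + 1;
  NumericVector dx(H * W * C * N);
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          double g = dy[idx4(ho, wo, c, n, Hout, Wout, C)] * inv;
          for (int j = 0; j < k; ++j)
            for (int i = 0; i < k; ++i)
              dx[idx4(ho * stride + i, wo * stride + j, c, n, H, W, C)] += g;
        }
  return dx;
}

// Bilinear resize, half-pixel centers (align_corners = FALSE).
static inline void src_coords(int o, int Out, int In, int& i0, int& i1,
                              double& w1) {
  double s = (In == Out) ? (double)o
    : ((o + 0.5) * ((double)In / Out) - 0.5);
  if (s < 0) s = 0;
  if (s > In - 1) s = In - 1;
  i0 = (int)s;
  i1 = (i0 + 1 < In) ? i0 + 1 : i0;
  w1 = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int H, int W, int C, int N,
                                  int Hout, int Wout) {
  NumericVector y(Hout * Wout * C * N);
  for (int wo = 0; wo < Wout; ++wo) {
    int w0, w1i; double ww;
    src_coords(wo, Wout, W, w0, w1i, ww);
    for (int ho = 0; ho < Hout; ++ho) {
      int h0, h1i; double wh;
      src_coords(ho, Hout, H, h0, h1i, wh);
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < C; ++c) {
          double v =
            (1 - wh) * (1 - ww) * x[idx4(h0, w0, c, n, H, W, C)] +
            wh * (1 - ww) * x[idx4(h1i, w0, c, n, H, W, C)] +
            (1 - wh) * ww * x[idx4(h0, w1i, c, n, H, W, C)] +
            wh * ww * x[idx4(h1i, w1i, c, n, H, W, C)];
          y[idx4(ho, wo, c, n, Hout, Wout, C)] = v;
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_grad(NumericVector dy, int H, int W, int C,
                                       int N, int Hout, int Wout) {
  NumericVector dx(H * W * C * N);
  for (int wo = 0; wo < Wout; ++wo) {
    int w0, w1i; double ww;
    src_coords(wo, Wout, W, w0, w1i, ww);
    for (int ho = 0; ho < Hout; ++ho) {
      int h0, h1i; double wh;
      src_coords(ho, Hout, H, h0, h1i, wh);
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < C; ++c) {
          double g = dy[idx4(ho, wo, c, n, Hout, Wout, C)];
          dx[idx4(h0, w0, c, n, H, W, C)] += (1 - wh) * (1 - ww) * g;
          dx[idx4(h1i, w0, c, n, H, W, C)] += wh * (1 - ww) * g;
          dx[idx4(h0, w1i, c, n, H, W, C)] += (1 - wh) * ww * g;
          dx[idx4(h1i, w1i, c, n, H, W, C)] += wh * ww * g;
        }
    }
  }
  return dx;
}

// Depthwise convolution (groups == C_in == C_out), direct evaluation.
// [[Rcpp::export]]
NumericVector cpp_dwconv(NumericVector x, NumericVector w, int H, int W,
                         int C, int N, int k, int pad, int stride,
                         int dil) {
  int Hout = (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  int Wout = (W + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  NumericVector y(Hout * Wout * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* wc = &w[k * k * c];
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          double s = 0.0;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j * dil;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i * dil;
              if (hi < 0 || hi >= H) continue;
              s += wc[i + k * j] * x[idx4(hi, wi, c, n, H, W, C)];
            }
          }
          y[idx4(ho, wo, c, n, Hout, Wout, C)] = s;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_dx(NumericVector dy, NumericVector w, int H,
                            int W, int C, int N, int k, int pad,
                            int stride, int dil) {
  int Hout = (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  int Wout = (W + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  NumericVector dx(H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* wc = &w[k * k * c];
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          double g = dy[idx4(ho, wo, c, n, Hout, Wout, C)];
          if (g == 0.0) continue;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j * dil;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i * dil;
              if (hi < 0 || hi >= H) continue;
              dx[idx4(hi, wi, c, n, H, W, C)] += g * wc[i + k * j];
            }
          }
        }
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_dw(NumericVector dy, NumericVector x, int H,
                            int W, int C, int N, int k, int pad,
                            int stride, int dil) {
  int Hout = (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  int Wout = (W + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  NumericVector dw(k * k * C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* wc = &dw[k * k * c];
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          double g = dy[idx4(ho, wo, c, n, Hout, Wout, C)];
          if (g == 0.0) continue;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j * dil;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i * dil;
              if (hi < 0 || hi >= H) continue;
              wc[i + k * j] += g * x[idx4(hi, wi, c, n, H, W, C)];
            }
          }
        }
    }
  return dw;
}

#include <R_ext/BLAS.h>

// Dense/grouped 2-D convolution: im2col + BLAS dgemm entirely in C++.
// x: (H, W, C, N); w: (k, k, C/g, Cout). Returns y: (Hout, Wout, Cout, N).
static void im2col_buf(const double* x, int H, int W, int C, int n,
                       int c0, int Cg, int k, int pad, int stride,
                       int dil, int Hout, int Wout, double* col) {
  // col is (k*k*Cg) x (Hout*Wout), rows kh fastest, then kw, then c
  for (int wo = 0; wo < Wout; ++wo)
    for (int ho = 0; ho < Hout; ++ho) {
      double* dst = col + (size_t)(ho + Hout * wo) * (k * k * Cg);
      for (int c = 0; c < Cg; ++c)
        for (int j = 0; j < k; ++j) {
          int wi = wo * stride - pad + j * dil;
          for (int i = 0; i < k; ++i) {
            int hi = ho * stride - pad + i * dil;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = x[idx4(hi, wi, c0 + c, n, H, W, C)];
            dst[i + k * (j + k * c)] = v;
          }
        }
    }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, int H,
                             int W, int C, int N, int k, int cout,
                             int groups, int pad, int stride, int dil) {
  int Hout = (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  int Wout = (W + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  int Cg = C / groups, Og = cout / groups;
  int KKC = k * k * Cg, M = Hout * Wout;
  NumericVector y((size_t)M * cout * N);
  std::vector<double> col((size_t)KKC * M);
  std::vector<double> ym((size_t)Og * M);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      im2col_buf(x.begin(), H, W, C, n, g * Cg, Cg, k, pad, stride, dil,
                 Hout, Wout, col.data());
      // ym (Og x M) = t(Wg) (Og x KKC) %*% col (KKC x M)
      const double* wg = w.begin() + (size_t)KKC * Og * g;
      F77_CALL(dgemm)("T", "N", &Og, &M, &KKC, &one, wg, &KKC,
                      col.data(), &KKC, &zero, ym.data(), &Og FCONE FCONE);
      double* yp = y.begin();
      for (int m = 0; m < M; ++m) {
        int ho = m % Hout, wo = m / Hout;
        for (int c = 0; c < Og; ++c)
          yp[idx4(ho, wo, g * Og + c, n, Hout, Wout, cout)] =
            ym[(size_t)c + (size_t)Og * m];
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector gr, NumericVector x, NumericVector w,
                    int H, int W, int C, int N, int k, int cout,
                    int groups, int pad, int stride, int dil) {
  int Hout = (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  int Wout = (W + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  int Cg = C / groups, Og = cout / groups;
  int KKC = k * k * Cg, M = Hout * Wout;
  NumericVector dx((size_t)H * W * C * N);
  NumericVector dw(w.size());
  std::vector<double> col((size_t)KKC * M);
  std::vector<double> gm((size_t)Og * M);
  std::vector<double> dcol((size_t)KKC * M);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      // gather gradient slice as (Og x M)
      const double* gp = gr.begin();
      for (int m = 0; m < M; ++m) {
        int ho = m % Hout, wo = m / Hout;
        for (int c = 0; c < Og; ++c)
          gm[(size_t)c + (size_t)Og * m] =
            gp[idx4(ho, wo, g * Og + c, n, Hout, Wout, cout)];
      }
      im2col_buf(x.begin(), H, W, C, n, g * Cg, Cg, k, pad, stride, dil,
                 Hout, Wout, col.data());
      // dWg (KKC x Og) += col (KKC x M) %*% t(gm) (M x Og)
      double* dwg = dw.begin() + (size_t)KKC * Og * g;
      F77_CALL(dgemm)("N", "T", &KKC, &Og, &M, &one, col.data(), &KKC,
                      gm.data(), &Og, &one, dwg, &KKC FCONE FCONE);
      // dcol (KKC x M) = Wg (KKC x Og) %*% gm (Og x M)
      const double* wg = w.begin() + (size_t)KKC * Og * g;
      F77_CALL(dgemm)("N", "N", &KKC, &M, &Og, &one, wg, &KKC, gm.data(),
                      &Og, &zero, dcol.data(), &KKC FCONE FCONE);
      // col2im accumulate
      double* dxp = dx.begin();
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          const double* src = dcol.data() +
            (size_t)(ho + Hout * wo) * KKC;
          for (int c = 0; c < Cg; ++c)
            for (int j = 0; j < k; ++j) {
              int wi = wo * stride - pad + j * dil;
              if (wi < 0 || wi >= W) continue;
              for (int i = 0; i < k; ++i) {
                int hi = ho * stride - pad + i * dil;
                if (hi < 0 || hi >= H) continue;
                dxp[idx4(hi, wi, g * Cg + c, n, H, W, C)] +=
                  src[i + k * (j + k * c)];
              }
            }
        }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
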
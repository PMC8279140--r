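// Low-level numerical kernels for the network engine and post-processing.
// Tensor layout everywhere: R arrays dim c(H, W, C, N), column-major, so the
// element (h, w, c, n) [0-based] lives at h + H*(w + W*(c + C*n)).
// Weight layout for conv: dim c(kh, kw, Cin/groups, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// Fill col (K x Ho*Wo) for sample n and channel range [c0, c0+nc).
// Row index = ki + kh*(kj + kw*c_rel) to match weight flattening.
static void im2col(const double* x, int H, int W, int C, int n,
                   int c0, int nc, int kh, int kw, int sh, int sw,
                   int pt, int pl, int Ho, int Wo, arma::mat& col) {
  col.zeros();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int out = ho + Ho * wo;
      const int hbase = ho * sh - pt;
      const int wbase = wo * sw - pl;
      double* cptr = col.colptr(out);
      for (int c = 0; c < nc; ++c) {
        const double* xc = x + H * (size_t)W * (c0 + c + (size_t)C * n);
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wbase + kj;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + H * (size_t)wi;
          double* dst = cptr + kh * (kj + kw * c);
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = hbase + ki;
            if (hi >= 0 && hi < H) dst[ki] = xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-add the columns back (adjoint of im2col).
static void col2im(const arma::mat& col, double* gx, int H, int W, int C, int n,
                   int c0, int nc, int kh, int kw, int sh, int sw,
                   int pt, int pl, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int out = ho + Ho * wo;
      const int hbase = ho * sh - pt;
      const int wbase = wo * sw - pl;
      const double* cptr = col.colptr(out);
      for (int c = 0; c < nc; ++c) {
        double* xc = gx + H * (size_t)W * (c0 + c + (size_t)C * n);
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wbase + kj;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + H * (size_t)wi;
          const double* src = cptr + kh * (kj + kw * c);
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = hbase + ki;
            if (hi >= 0 && hi < H) xcol[hi] += src[ki];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             Nullable<NumericVector> bias,
                             int sh, int sw, int pt, int pl,
                             int Ho, int Wo, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cin_g = wdim[2], Cout = wdim[3];
  const int cout_g = Cout / groups;
  const int K = kh * kw * cin_g;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  arma::mat col(K, (size_t)Ho * Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp, H, W, C, n, g * cin_g, cin_g, kh, kw, sh, sw, pt, pl, Ho, Wo, col);
      const arma::mat wm(const_cast<double*>(w.begin()) + (size_t)g * cout_g * K,
                         K, cout_g, false, true);
      arma::mat ym = col.t() * wm;  // (Ho*Wo) x cout_g
      std::memcpy(yp + (size_t)Ho * Wo * (g * cout_g + (size_t)Cout * n),
                  ym.memptr(), sizeof(double) * ym.n_elem);
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    const size_t hw = (size_t)Ho * Wo;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        double* yc = yp + hw * (c + (size_t)Cout * n);
        const double bc = b[c];
        for (size_t i = 0; i < hw; ++i) yc[i] += bc;
      }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector gy, bool has_bias,
                    int sh, int sw, int pt, int pl,
                    int Ho, int Wo, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cin_g = wdim[2], Cout = wdim[3];
  const int cout_g = Cout / groups;
  const int K = kh * kw * cin_g;
  NumericVector gx((size_t)H * W * C * N);
  NumericVector gw(w.size());
  NumericVector gb(has_bias ? Cout : 0);
  arma::mat col(K, (size_t)Ho * Wo);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp, H, W, C, n, g * cin_g, cin_g, kh, kw, sh, sw, pt, pl, Ho, Wo, col);
      const arma::mat wm(const_cast<double*>(w.begin()) + (size_t)g * cout_g * K,
                         K, cout_g, false, true);
      const arma::mat gym(const_cast<double*>(gy.begin()) +
                          (size_t)Ho * Wo * (g * cout_g + (size_t)Cout * n),
                          (size_t)Ho * Wo, cout_g, false, true);
      arma::mat gwm(gw.begin() + (size_t)g * cout_g * K, K, cout_g, false, true);
      gwm += col * gym;
      arma::mat gcol = wm * gym.t();  // K x Ho*Wo
      col2im(gcol, gx.begin(), H, W, C, n, g * cin_g, cin_g,
             kh, kw, sh, sw, pt, pl, Ho, Wo);
    }
  }
  if (has_bias) {
    const size_t hw = (size_t)Ho * Wo;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        const double* gc = gy.begin() + hw * (c + (size_t)Cout * n);
        double s = 0.0;
        for (size_t i = 0; i < hw; ++i) s += gc[i];
        gb[c] += s;
      }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim,
                     int kh, int kw, int sh, int sw, int pt, int pl,
                     int Ho, int Wo) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector arg(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * sw - pl + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * sh - pt + ki;
              if (hi < 0 || hi >= H) continue;
              const double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; bi = hi + H * wi; }
            }
          }
          const size_t o = ho + Ho * ((size_t)wo + Wo * (c + (size_t)C * n));
          yp[o] = (bi < 0) ? 0.0 : best;
          ap[o] = bi;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector arg,
                              IntegerVector xdim, IntegerVector ydim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hwy = (size_t)ydim[0] * ydim[1];
  NumericVector gx((size_t)H * W * C * N);
  double* gxp = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t yoff = hwy * (c + (size_t)C * n);
      double* gxc = gxp + (size_t)H * W * (c + (size_t)C * n);
      for (size_t i = 0; i < hwy; ++i) {
        const int bi = arg[yoff + i];
        if (bi >= 0) gxc[bi] += gy[yoff + i];
      }
    }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, IntegerVector xdim,
                              int kh, int kw, int sh, int sw, int pt, int pl,
                              int Ho, int Wo) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  const double inv = 1.0 / (kh * kw);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0.0;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * sw - pl + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * sh - pt + ki;
              if (hi >= 0 && hi < H) s += xc[hi + (size_t)H * wi];
            }
          }
          yp[ho + Ho * ((size_t)wo + Wo * (c + (size_t)C * n))] = s * inv;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector gy, IntegerVector xdim,
                              int kh, int kw, int sh, int sw, int pt, int pl,
                              int Ho, int Wo) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector gx((size_t)H * W * C * N);
  const double inv = 1.0 / (kh * kw);
  double* gxp = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gxc = gxp + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gy[ho + Ho * ((size_t)wo + Wo * (c + (size_t)C * n))] * inv;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * sw - pl + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * sh - pt + ki;
              if (hi >= 0 && hi < H) gxc[hi + (size_t)H * wi] += g;
            }
          }
        }
    }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn_fwd(NumericVector x, IntegerVector xdim, int f) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H * f, Wo = W * f;
  NumericVector y((size_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      double* yc = yp + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const double* xcol = xc + (size_t)H * (wo / f);
        double* ycol = yc + (size_t)Ho * wo;
        for (int ho = 0; ho < Ho; ++ho) ycol[ho] = xcol[ho / f];
      }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn_bwd(NumericVector gy, IntegerVector xdim, int f) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H * f, Wo = W * f;
  NumericVector gx((size_t)H * W * C * N);
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = gxp + (size_t)H * W * (c + (size_t)C * n);
      const double* yc = gp + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double* xcol = xc + (size_t)H * (wo / f);
        const double* ycol = yc + (size_t)Ho * wo;
        for (int ho = 0; ho < Ho; ++ho) xcol[ho / f] += ycol[ho];
      }
    }
  gx.attr("dim") = xdim;
  return gx;
}

// 8-connected component labelling of a binary matrix (H x W, values 0/1).
// Returns an integer matrix of labels (0 = background, components 1..k).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int w0 = 0; w0 < W; ++w0)
    for (int h0 = 0; h0 < H; ++h0) {
      if (mask(h0, w0) == 0 || lab(h0, w0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(h0 + H * w0);
      lab(h0, w0) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int h = p % H, w = p / H;
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            if (dh == 0 && dw == 0) continue;
            const int hh = h + dh, ww = w + dw;
            if (hh < 0 || hh >= H || ww < 0 || ww >= W) continue;
            if (mask(hh, ww) != 0 && lab(hh, ww) == 0) {
              lab(hh, ww) = next;
              stack.push_back(hh + H * ww);
            }
          }
      }
    }
  return lab;
}
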
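// Low-level numeric kernels for the segmentation network and mask morphology.
// Tensors are R arrays of dim (H, W, C, N), column-major doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword t4(arma::uword h, arma::uword w, arma::uword c,
                             arma::uword n, arma::uword H, arma::uword W,
                             arma::uword C) {
  return h + H * (w + W * (c + C * n));
}

// im2col for one sample over an output-row strip [r0, r1).
// Row layout inside cols: output pixel (i, j) -> (i - r0) + (r1 - r0) * j
// (i fastest, matching the column-major tensor layout, so the stride-1 path
// reduces to contiguous copies).
// Column layout: q = c*(kh*kw) + ki*kw + kj  (must match weight layout in R).
static void im2col_strip(const double* x, arma::uword H, arma::uword W,
                         arma::uword C, arma::uword n, int kh, int kw,
                         int stride, int pad, arma::uword Wo,
                         arma::uword r0, arma::uword r1, arma::mat& cols) {
  const arma::uword K = (arma::uword)kh * kw * C;
  const arma::uword S = r1 - r0;
  cols.set_size(S * Wo, K);
  for (arma::uword c = 0; c < C; ++c) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const arma::uword q = c * (arma::uword)(kh * kw) + (arma::uword)ki * kw + kj;
        double* dst = cols.colptr(q);
        if (stride == 1) {
          // source rows ih = i - pad + ki are consecutive in i
          const long h0 = (long)r0 - pad + ki;
          long lo = std::max(0L, -h0);              // first valid i offset
          long hi = std::min((long)S, (long)H - h0); // one past last valid
          if (lo > (long)S) lo = S;
          if (hi < 0) hi = 0;
          for (arma::uword j = 0; j < Wo; ++j) {
            const long iw = (long)j - pad + kj;
            double* d = dst + S * j;
            if (iw < 0 || iw >= (long)W) {
              std::fill(d, d + S, 0.0);
              continue;
            }
            if (lo > 0) std::fill(d, d + lo, 0.0);
            if (hi > lo) {
              const double* s =
                  x + t4((arma::uword)(h0 + lo), (arma::uword)iw, c, n, H, W, C);
              std::copy(s, s + (hi - lo), d + lo);
            }
            if ((long)S > hi) std::fill(d + hi, d + S, 0.0);
          }
        } else {
          for (arma::uword j = 0; j < Wo; ++j) {
            const long iw = (long)j * stride - pad + kj;
            double* d = dst + S * j;
            for (arma::uword i = r0; i < r1; ++i) {
              const long ih = (long)i * stride - pad + ki;
              double v = 0.0;
              if (ih >= 0 && ih < (long)H && iw >= 0 && iw < (long)W)
                v = x[t4((arma::uword)ih, (arma::uword)iw, c, n, H, W, C)];
              d[i - r0] = v;
            }
          }
        }
      }
    }
  }
}

static arma::uword strip_rows(arma::uword Wo, arma::uword K) {
  // cap the im2col buffer at ~2^24 doubles (128 MB)
  arma::uword cap = (arma::uword)1 << 24;
  arma::uword per_row = Wo * K;
  arma::uword s = per_row ? std::max<arma::uword>(1, cap / per_row) : 1;
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericMatrix w, NumericVector b,
                            int kh, int kw, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], N = d[3];
  arma::uword Ho = (H + 2 * pad - kh) / stride + 1;
  arma::uword Wo = (W + 2 * pad - kw) / stride + 1;
  arma::uword Cout = w.ncol();
  const arma::mat wm(const_cast<double*>(w.begin()), w.nrow(), w.ncol(), false);
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols;
  arma::uword srows = strip_rows(Wo, (arma::uword)kh * kw * C);
  for (arma::uword n = 0; n < N; ++n) {
    for (arma::uword r0 = 0; r0 < Ho; r0 += srows) {
      arma::uword r1 = std::min(Ho, r0 + srows);
      im2col_strip(x.begin(), H, W, C, n, kh, kw, stride, pad, Wo, r0, r1, cols);
      arma::mat ym = cols * wm;  // (strip*Wo) x Cout, i fastest
      const arma::uword S = r1 - r0;
      for (arma::uword co = 0; co < Cout; ++co) {
        const double* src = ym.colptr(co);
        const double bb = b[co];
        for (arma::uword j = 0; j < Wo; ++j) {
          double* dst = &y[t4(r0, j, co, n, Ho, Wo, Cout)];
          const double* s = src + S * j;
          for (arma::uword i = 0; i < S; ++i) dst[i] = s[i] + bb;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericMatrix w, NumericVector gy,
                   int kh, int kw, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dy = gy.attr("dim");
  arma::uword Ho = dy[0], Wo = dy[1], Cout = dy[2];
  const arma::mat wm(const_cast<double*>(w.begin()), w.nrow(), w.ncol(), false);
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  arma::mat gw(w.nrow(), w.ncol(), arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat cols;
  arma::uword srows = strip_rows(Wo, (arma::uword)kh * kw * C);
  for (arma::uword n = 0; n < N; ++n) {
    for (arma::uword r0 = 0; r0 < Ho; r0 += srows) {
      arma::uword r1 = std::min(Ho, r0 + srows);
      const arma::uword S = r1 - r0;
      arma::mat gym(S * Wo, Cout);
      for (arma::uword co = 0; co < Cout; ++co) {
        double* dst = gym.colptr(co);
        double acc = 0.0;
        for (arma::uword j = 0; j < Wo; ++j) {
          const double* s = &gy[t4(r0, j, co, n, Ho, Wo, Cout)];
          double* d = dst + S * j;
          for (arma::uword i = 0; i < S; ++i) { d[i] = s[i]; acc += s[i]; }
        }
        gb[co] += acc;
      }
      im2col_strip(x.begin(), H, W, C, n, kh, kw, stride, pad, Wo, r0, r1, cols);
      gw += cols.t() * gym;
      arma::mat gcols = gym * wm.t();  // (strip*Wo) x K, i fastest
      // col2im scatter-add
      for (arma::uword c = 0; c < C; ++c)
        for (int ki = 0; ki < kh; ++ki)
          for (int kj = 0; kj < kw; ++kj) {
            const arma::uword q = c * (arma::uword)(kh * kw) + (arma::uword)ki * kw + kj;
            const double* src = gcols.colptr(q);
            if (stride == 1) {
              const long h0 = (long)r0 - pad + ki;
              long lo = std::max(0L, -h0);
              long hi = std::min((long)S, (long)H - h0);
              if (hi < lo) continue;
              for (arma::uword j = 0; j < Wo; ++j) {
                const long iw = (long)j - pad + kj;
                if (iw < 0 || iw >= (long)W) continue;
                double* d =
                    &gx[t4((arma::uword)(h0 + lo), (arma::uword)iw, c, n, H, W, C)];
                const double* s = src + S * j + lo;
                for (long i = 0; i < hi - lo; ++i) d[i] += s[i];
              }
            } else {
              for (arma::uword j = 0; j < Wo; ++j) {
                const long iw = (long)j * stride - pad + kj;
                if (iw < 0 || iw >= (long)W) continue;
                for (arma::uword i = r0; i < r1; ++i) {
                  const long ih = (long)i * stride - pad + ki;
                  if (ih < 0 || ih >= (long)H) continue;
                  gx[t4((arma::uword)ih, (arma::uword)iw, c, n, H, W, C)] +=
                      src[S * j + (i - r0)];
                }
              }
            }
          }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = wrap(gw), _["gb"] = wrap(gb));
}

// depthwise 3x3, stride 1, pad 1; w is (9, C)
// [[Rcpp::export]]
NumericVector cpp_dwconv_fw(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double* wc = &w(0, c);
      for (arma::uword j = 0; j < W; ++j)
        for (arma::uword i = 0; i < H; ++i) {
          double acc = b[c];
          for (int ki = 0; ki < 3; ++ki) {
            long ih = (long)i - 1 + ki;
            if (ih < 0 || ih >= (long)H) continue;
            for (int kj = 0; kj < 3; ++kj) {
              long iw = (long)j - 1 + kj;
              if (iw < 0 || iw >= (long)W) continue;
              acc += wc[ki * 3 + kj] *
                     x[t4((arma::uword)ih, (arma::uword)iw, c, n, H, W, C)];
            }
          }
          y[t4(i, j, c, n, H, W, C)] = acc;
        }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bw(NumericVector x, NumericMatrix w, NumericVector gy) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  NumericMatrix gw(9, C);
  NumericVector gb(C);
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double* wc = &w(0, c);
      for (arma::uword j = 0; j < W; ++j)
        for (arma::uword i = 0; i < H; ++i) {
          const double g = gy[t4(i, j, c, n, H, W, C)];
          gb[c] += g;
          for (int ki = 0; ki < 3; ++ki) {
            long ih = (long)i - 1 + ki;
            if (ih < 0 || ih >= (long)H) continue;
            for (int kj = 0; kj < 3; ++kj) {
              long iw = (long)j - 1 + kj;
              if (iw < 0 || iw >= (long)W) continue;
              arma::uword q = t4((arma::uword)ih, (arma::uword)iw, c, n, H, W, C);
              gw(ki * 3 + kj, c) += g * x[q];
              gx[q] += g * wc[ki * 3 + kj];
            }
          }
        }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// transposed conv 2x2 stride 2; w dim (Cin, Cout, 2, 2) flattened array
// [[Rcpp::export]]
NumericVector cpp_convt2_fw(NumericVector x, NumericVector w, NumericVector b,
                            int Cout) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], Cin = d[2], N = d[3];
  arma::uword Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Ho * Wo * (arma::uword)Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (arma::uword n = 0; n < N; ++n)
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj) {
        // W_dd: Cin x Cout slice
        arma::mat wdd(Cin, Cout);
        for (arma::uword ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            wdd(ci, co) = w[ci + Cin * (co + (arma::uword)Cout * (di + 2 * dj))];
        arma::mat xm(H * W, Cin);
        for (arma::uword ci = 0; ci < Cin; ++ci) {
          double* dst = xm.colptr(ci);
          for (arma::uword j = 0; j < W; ++j)
            for (arma::uword i = 0; i < H; ++i)
              dst[i + H * j] = x[t4(i, j, ci, n, H, W, Cin)];
        }
        arma::mat ym = xm * wdd;  // HW x Cout
        for (int co = 0; co < Cout; ++co) {
          const double* src = ym.colptr(co);
          for (arma::uword j = 0; j < W; ++j)
            for (arma::uword i = 0; i < H; ++i)
              y[t4(2 * i + di, 2 * j + dj, co, n, Ho, Wo, Cout)] =
                  src[i + H * j] + b[co];
        }
      }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int Cout) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], Cin = d[2], N = d[3];
  arma::uword Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  for (arma::uword n = 0; n < N; ++n) {
    arma::mat xm(H * W, Cin);
    for (arma::uword ci = 0; ci < Cin; ++ci) {
      double* dst = xm.colptr(ci);
      for (arma::uword j = 0; j < W; ++j)
        for (arma::uword i = 0; i < H; ++i)
          dst[i + H * j] = x[t4(i, j, ci, n, H, W, Cin)];
    }
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj) {
        arma::mat wdd(Cin, Cout);
        for (arma::uword ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            wdd(ci, co) = w[ci + Cin * (co + (arma::uword)Cout * (di + 2 * dj))];
        arma::mat gym(H * W, Cout);
        for (int co = 0; co < Cout; ++co) {
          double* dst = gym.colptr(co);
          double acc = 0.0;
          for (arma::uword j = 0; j < W; ++j)
            for (arma::uword i = 0; i < H; ++i) {
              double v = gy[t4(2 * i + di, 2 * j + dj, co, n, Ho, Wo, Cout)];
              dst[i + H * j] = v;
              acc += v;
            }
          gb[co] += acc;
        }
        arma::mat gxm = gym * wdd.t();
        for (arma::uword ci = 0; ci < Cin; ++ci) {
          const double* src = gxm.colptr(ci);
          for (arma::uword j = 0; j < W; ++j)
            for (arma::uword i = 0; i < H; ++i)
              gx[t4(i, j, ci, n, H, W, Cin)] += src[i + H * j];
        }
        arma::mat gwdd = xm.t() * gym;
        for (arma::uword ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            gw[ci + Cin * (co + (arma::uword)Cout * (di + 2 * dj))] +=
                gwdd(ci, co);
      }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; returns pooled values and argmax code 0..3
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], N = d[3];
  arma::uword Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c)
      for (arma::uword j = 0; j < Wo; ++j)
        for (arma::uword i = 0; i < Ho; ++i) {
          double best = -1e300;
          int bi = 0;
          for (int di = 0; di < 2; ++di)
            for (int dj = 0; dj < 2; ++dj) {
              double v = x[t4(2 * i + di, 2 * j + dj, c, n, H, W, C)];
              if (v > best) { best = v; bi = di + 2 * dj; }
            }
          arma::uword q = t4(i, j, c, n, Ho, Wo, C);
          y[q] = best;
          idx[q] = bi;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(IntegerVector idx, NumericVector gy,
                              int H, int W) {
  IntegerVector d = gy.attr("dim");
  arma::uword Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector gx((arma::uword)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c)
      for (arma::uword j = 0; j < Wo; ++j)
        for (arma::uword i = 0; i < Ho; ++i) {
          arma::uword q = t4(i, j, c, n, Ho, Wo, C);
          int di = idx[q] % 2, dj = idx[q] / 2;
          gx[t4(2 * i + di, 2 * j + dj, c, n, H, W, C)] += gy[q];
        }
  return gx;
}

// per-channel sum and sum-of-squares over (H, W, N)
// [[Rcpp::export]]
List cpp_channel_stats(NumericVector x) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], N = d[3];
  arma::vec s(C, arma::fill::zeros), ss(C, arma::fill::zeros);
  const arma::uword plane = H * W;
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double* p = &x[plane * (c + C * n)];
      double a = 0.0, b = 0.0;
      for (arma::uword k = 0; k < plane; ++k) { a += p[k]; b += p[k] * p[k]; }
      s[c] += a; ss[c] += b;
    }
  return List::create(_["sum"] = wrap(s), _["sumsq"] = wrap(ss));
}

// y = x * mul[c] + add[c], broadcast per channel
// [[Rcpp::export]]
NumericVector cpp_scale_shift(NumericVector x, NumericVector mul,
                              NumericVector add) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const arma::uword plane = H * W;
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double* p = &x[plane * (c + C * n)];
      double* q = &y[plane * (c + C * n)];
      const double m = mul[c], a = add[c];
      for (arma::uword k = 0; k < plane; ++k) q[k] = p[k] * m + a;
    }
  return y;
}

// batch-norm backward given xhat, per-channel gamma and inv = 1/sd
// [[Rcpp::export]]
List cpp_bn_bw(NumericVector gy, NumericVector xhat, NumericVector gamma,
               NumericVector inv) {
  IntegerVector d = gy.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], N = d[3];
  const arma::uword plane = H * W;
  const double m = (double)plane * N;
  arma::vec ggamma(C, arma::fill::zeros), gbeta(C, arma::fill::zeros);
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double* g = &gy[plane * (c + C * n)];
      const double* xh = &xhat[plane * (c + C * n)];
      double a = 0.0, b = 0.0;
      for (arma::uword k = 0; k < plane; ++k) {
        a += g[k] * xh[k]; b += g[k];
      }
      ggamma[c] += a; gbeta[c] += b;
    }
  NumericVector gx(gy.size());
  gx.attr("dim") = d;
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double* g = &gy[plane * (c + C * n)];
      const double* xh = &xhat[plane * (c + C * n)];
      double* o = &gx[plane * (c + C * n)];
      const double gamc = gamma[c], invc = inv[c];
      const double s1 = ggamma[c] * gamc, s0 = gbeta[c] * gamc;
      for (arma::uword k = 0; k < plane; ++k)
        o[k] = invc / m * (m * gamc * g[k] - s0 - xh[k] * s1);
    }
  return List::create(_["gx"] = gx, _["ggamma"] = wrap(ggamma),
                      _["gbeta"] = wrap(gbeta));
}

// connected-component labeling, raster order of first pixel (row-major),
// connectivity 4 or 8; labels 1..k, background 0
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int>> nb;
  nb.push_back({-1, 0}); nb.push_back({1, 0});
  nb.push_back({0, -1}); nb.push_back({0, 1});
  if (connectivity == 8) {
    nb.push_back({-1, -1}); nb.push_back({-1, 1});
    nb.push_back({1, -1}); nb.push_back({1, 1});
  }
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int i = 0; i < H; ++i)          // row-major scan
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto p = stack.back(); stack.pop_back();
        for (auto& d : nb) {
          int ii = p.first + d.first, jj = p.second + d.second;
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back({ii, jj});
          }
        }
      }
    }
  return lab;
}

// binary dilation with a k x k all-ones kernel anchored at floor(k/2):
// y(i,j) = max over u,v in [-a, k-1-a] of x(i+u, j+v), a = floor(k/2)
// [[Rcpp::export]]
IntegerMatrix cpp_dilate_ones(IntegerMatrix x, int k) {
  int H = x.nrow(), W = x.ncol(), a = k / 2;
  IntegerMatrix tmp(H, W), y(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      int v = 0;
      for (int u = -a; u <= k - 1 - a && !v; ++u) {
        int ii = i + u;
        if (ii >= 0 && ii < H && x(ii, j)) v = 1;
      }
      tmp(i, j) = v;
    }
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      int v = 0;
      for (int u = -a; u <= k - 1 - a && !v; ++u) {
        int jj = j + u;
        if (jj >= 0 && jj < W && tmp(i, jj)) v = 1;
      }
      y(i, j) = v;
    }
  return y;
}

// crack-edge perimeter per label: number of pixel edges between a labelled
// pixel and background/other-label/image border
// [[Rcpp::export]]
NumericVector cpp_crack_perimeter(IntegerMatrix lab, int nlab) {
  int H = lab.nrow(), W = lab.ncol();
  NumericVector per(nlab);
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      int l = lab(i, j);
      if (l == 0) continue;
      for (int q = 0; q < 4; ++q) {
        int ii = i + di[q], jj = j + dj[q];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W || lab(ii, jj) != l)
          per[l - 1] += 1.0;
      }
    }
  return per;
}
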
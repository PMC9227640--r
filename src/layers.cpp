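// Small dense layer helpers kept out of R's allocator hot path: 3x3 "same"
// 2D convolution, LeakyReLU, and per-channel affine maps for BatchNorm.
#include <Rcpp.h>
using namespace Rcpp;

// x: [H, W, Cin], w: [3, 3, Cin, Cout], zero padding, stride 1.
// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, IntegerVector dimx,
                            NumericVector w, NumericVector b) {
  const int H = dimx[0], W = dimx[1], Cin = dimx[2];
  const int Cout = b.size();
  NumericVector y((R_xlen_t)H * W * Cout);
  for (int co = 0; co < Cout; ++co) {
    double* yc = y.begin() + (size_t)H * W * co;
    std::fill(yc, yc + (size_t)H * W, b[co]);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x.begin() + (size_t)H * W * ci;
      const double* wt = w.begin() + 9 * (ci + (size_t)Cin * co);
      for (int kw = 0; kw < 3; ++kw)
        for (int kh = 0; kh < 3; ++kh) {
          const double wv = wt[kh + 3 * kw];
          if (wv == 0.0) continue;
          const int oh = kh - 1, ow = kw - 1;
          const int w0 = std::max(0, -ow), w1 = std::min(W, W - ow);
          const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
          for (int ww = w0; ww < w1; ++ww) {
            const double* src = xc + (size_t)H * (ww + ow) + oh;
            double* dst = yc + (size_t)H * ww;
            for (int hh = h0; hh < h1; ++hh) dst[hh] += wv * src[hh];
          }
        }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout);
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, IntegerVector dimx, NumericVector w,
                   IntegerVector dimw, NumericVector gy) {
  const int H = dimx[0], W = dimx[1], Cin = dimx[2];
  const int Cout = dimw[3];
  NumericVector gx((R_xlen_t)H * W * Cin);
  NumericVector gw((R_xlen_t)9 * Cin * Cout);
  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gy.begin() + (size_t)H * W * co;
    double sb = 0.0;
    for (size_t i = 0; i < (size_t)H * W; ++i) sb += gc[i];
    gb[co] = sb;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x.begin() + (size_t)H * W * ci;
      double* gxc = gx.begin() + (size_t)H * W * ci;
      const double* wt = w.begin() + 9 * (ci + (size_t)Cin * co);
      double* gwt = gw.begin() + 9 * (ci + (size_t)Cin * co);
      for (int kw = 0; kw < 3; ++kw)
        for (int kh = 0; kh < 3; ++kh) {
          const double wv = wt[kh + 3 * kw];
          const int oh = kh - 1, ow = kw - 1;
          const int w0 = std::max(0, -ow), w1 = std::min(W, W - ow);
          const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
          double acc = 0.0;
          for (int ww = w0; ww < w1; ++ww) {
            const double* src = xc + (size_t)H * (ww + ow) + oh;
            double* gdst = gxc + (size_t)H * (ww + ow) + oh;
            const double* g = gc + (size_t)H * ww;
            for (int hh = h0; hh < h1; ++hh) {
              acc += src[hh] * g[hh];
              gdst[hh] += wv * g[hh];
            }
          }
          gwt[kh + 3 * kw] += acc;
        }
    }
  }
  gx.attr("dim") = dimx;
  gw.attr("dim") = dimw;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector lrelu_fw_cpp(NumericVector x, double slope) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = x[i];
    y[i] = v > 0 ? v : slope * v;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector lrelu_bw_cpp(NumericVector x, NumericVector g, double slope) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? g[i] : slope * g[i];
  y.attr("dim") = x.attr("dim");
  return y;
}

// y[i] = x[i] * scale[c] + shift[c], channels = trailing dimension.
// [[Rcpp::export]]
NumericVector channel_affine_cpp(NumericVector x, NumericVector scale,
                                 NumericVector shift) {
  const int C = scale.size();
  const size_t N = x.size() / C;
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    const double s = scale[c], t = shift[c];
    const double* xi = x.begin() + N * c;
    double* yi = y.begin() + N * c;
    for (size_t i = 0; i < N; ++i) yi[i] = xi[i] * s + t;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// per-channel sums and sums of squares
// [[Rcpp::export]]
List channel_moments_cpp(NumericVector x, int C) {
  const size_t N = x.size() / C;
  NumericVector s1(C), s2(C);
  for (int c = 0; c < C; ++c) {
    const double* xi = x.begin() + N * c;
    double a = 0, b = 0;
    for (size_t i = 0; i < N; ++i) { a += xi[i]; b += xi[i] * xi[i]; }
    s1[c] = a; s2[c] = b;
  }
  return List::create(_["s1"] = s1, _["s2"] = s2, _["n"] = (double)N);
}

// BatchNorm train-mode input gradient:
// gx[i] = k[c] * (g[i] - gmean[c] - xhat[i] * hmean[c])
// [[Rcpp::export]]
NumericVector bn_bw_train_cpp(NumericVector g, NumericVector xhat,
                              NumericVector k, NumericVector gmean,
                              NumericVector hmean) {
  const int C = k.size();
  const size_t N = g.size() / C;
  NumericVector y(g.size());
  for (int c = 0; c < C; ++c) {
    const double kk = k[c], gm = gmean[c], hm = hmean[c];
    const double* gi = g.begin() + N * c;
    const double* xi = xhat.begin() + N * c;
    double* yi = y.begin() + N * c;
    for (size_t i = 0; i < N; ++i) yi[i] = kk * (gi[i] - gm - xi[i] * hm);
  }
  y.attr("dim") = g.attr("dim");
  return y;
}

// per-channel dot products: sum_i g[i]*xhat[i] and sum_i g[i]
// [[Rcpp::export]]
List channel_dots_cpp(NumericVector g, NumericVector xhat, int C) {
  const size_t N = g.size() / C;
  NumericVector dg(C), dgx(C);
  for (int c = 0; c < C; ++c) {
    const double* gi = g.begin() + N * c;
    const double* xi = xhat.begin() + N * c;
    double a = 0, b = 0;
    for (size_t i = 0; i < N; ++i) { a += gi[i]; b += gi[i] * xi[i]; }
    dg[c] = a; dgx[c] = b;
  }
  return List::create(_["sum_g"] = dg, _["sum_gx"] = dgx);
}

// Fused BatchNorm + LeakyReLU forward: given per-channel mean and inverse
// standard deviation, returns both the normalized xhat (cached for the
// backward pass) and the activated output in one traversal.
// [[Rcpp::export]]
List bn_act_fw_cpp(NumericVector x, NumericVector mu, NumericVector inv,
                   NumericVector gamma, NumericVector beta, double slope) {
  const int C = mu.size();
  const size_t N = x.size() / C;
  NumericVector xhat(x.size()), act(x.size());
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], iv = inv[c], g = gamma[c], bb = beta[c];
    const double* xi = x.begin() + N * c;
    double* xh = xhat.begin() + N * c;
    double* ai = act.begin() + N * c;
    for (size_t i = 0; i < N; ++i) {
      const double h = (xi[i] - m) * iv;
      xh[i] = h;
      const double y = h * g + bb;
      ai[i] = y > 0 ? y : slope * y;
    }
  }
  xhat.attr("dim") = x.attr("dim");
  act.attr("dim") = x.attr("dim");
  return List::create(_["xhat"] = xhat, _["act"] = act);
}

// Backward of LeakyReLU into BatchNorm's affine stage: masks the upstream
// gradient by the activation sign and accumulates the per-channel sums
// needed for the BatchNorm parameter/input gradients.
// [[Rcpp::export]]
List bn_act_bw_cpp(NumericVector g, NumericVector act, NumericVector xhat,
                   double slope, int C) {
  const size_t N = g.size() / C;
  NumericVector gm(g.size()), sum_g(C), sum_gx(C);
  for (int c = 0; c < C; ++c) {
    const double* gi = g.begin() + N * c;
    const double* ai = act.begin() + N * c;
    const double* xh = xhat.begin() + N * c;
    double* gmi = gm.begin() + N * c;
    double a = 0, b = 0;
    for (size_t i = 0; i < N; ++i) {
      const double v = ai[i] > 0 ? gi[i] : slope * gi[i];
      gmi[i] = v;
      a += v; b += v * xh[i];
    }
    sum_g[c] = a; sum_gx[c] = b;
  }
  gm.attr("dim") = g.attr("dim");
  return List::create(_["gmasked"] = gm, _["sum_g"] = sum_g,
                      _["sum_gx"] = sum_gx);
}
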
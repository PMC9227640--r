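// Specialized 3x3x3 stride-1 "same" convolution used by the decoder and the
// post-Sobel scale-fixing layer. Works on an explicitly zero-padded copy and
// accumulates one output line at a time; the arithmetic cores live in
// conv_cores.inc and are dispatched to an AVX2 build when the CPU allows.
#include <Rcpp.h>
#include "conv_cores.h"
using namespace Rcpp;

static void pad_input(const double* x, double* xp, int D, int H, int W, int C) {
  const int Dp = D + 2, Hp = H + 2, Wp = W + 2;
  std::fill(xp, xp + (size_t)Dp * Hp * Wp * C, 0.0);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double* src = x + (size_t)D * (h + (size_t)H * (w + (size_t)W * c));
        double* dst = xp + 1 + (size_t)Dp * ((h + 1) + (size_t)Hp * ((w + 1) + (size_t)Wp * c));
        std::copy(src, src + D, dst);
      }
}

// [[Rcpp::export]]
NumericVector conv3s1_fw_cpp(NumericVector x, IntegerVector dimx,
                             NumericVector w, NumericVector b) {
  const int D = dimx[0], H = dimx[1], W = dimx[2], C = dimx[3];
  const int Cout = b.size();
  std::vector<double> xp((size_t)(D + 2) * (H + 2) * (W + 2) * C);
  pad_input(x.begin(), xp.data(), D, H, W, C);
  NumericVector y((R_xlen_t)D * H * W * Cout);
  CONV_DISPATCH(conv3s1_core, xp.data(), w.begin(), b.begin(), y.begin(),
                D, H, W, C, Cout);
  y.attr("dim") = IntegerVector::create(D, H, W, Cout);
  return y;
}

// [[Rcpp::export]]
List conv3s1_bw_cpp(NumericVector x, IntegerVector dimx, NumericVector w,
                    NumericVector gy, bool need_gx) {
  const int D = dimx[0], H = dimx[1], W = dimx[2], Cin = dimx[3];
  const size_t N = (size_t)D * H * W;
  const int Cout = (int)(gy.size() / N);
  const int Dp = D + 2, Hp = H + 2, Wp = W + 2;
  const size_t chan = (size_t)Dp * Hp * Wp;

  std::vector<double> xp(chan * Cin);
  pad_input(x.begin(), xp.data(), D, H, W, Cin);
  NumericVector gw((R_xlen_t)27 * Cin * Cout);
  NumericVector gb(Cout);
  CONV_DISPATCH(conv3s1_gw_core, xp.data(), gy.begin(), gw.begin(),
                gb.begin(), D, H, W, Cin, Cout);

  NumericVector gx;
  if (need_gx) {
    // gx = same-shape convolution of gy with the spatially flipped kernel,
    // channels transposed: wflip[k', co, ci] = w[rev k', ci, co]
    std::vector<double> wflip((size_t)27 * Cout * Cin);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        for (int k = 0; k < 27; ++k) {
          const int kd = k % 3, kh = (k / 3) % 3, kw = k / 9;
          wflip[(2 - kd) + 3 * ((2 - kh) + 3 * (2 - kw)) +
                27 * (co + (size_t)Cout * ci)] =
              w[k + 27 * (ci + (size_t)Cin * co)];
        }
    std::vector<double> gp(chan * Cout);
    pad_input(gy.begin(), gp.data(), D, H, W, Cout);
    std::vector<double> zero(Cin, 0.0);
    gx = NumericVector((R_xlen_t)N * Cin);
    CONV_DISPATCH(conv3s1_core, gp.data(), wflip.data(), zero.data(),
                  gx.begin(), D, H, W, Cout, Cin);
    gx.attr("dim") = dimx;
  }
  gw.attr("dim") = IntegerVector::create(3, 3, 3, Cin, Cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
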
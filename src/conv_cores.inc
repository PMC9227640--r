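// Computational cores for the specialized convolutions. This file is
// compiled twice: once with baseline flags (suffix _base) and once with
// -mavx2 -mfma (suffix _avx2); callers pick a variant at runtime via
// __builtin_cpu_supports. NAME(f) is defined by the including TU.

// y[d,h,w,co] = b[co] + sum_{kd,kh,kw,ci} w[kd,kh,kw,ci,co] xpad[d+kd,h+kh,w+kw,ci]
void NAME(conv3s1_core)(const double* xp, const double* w, const double* b,
                        double* y, int D, int H, int W, int Cin, int Cout) {
  const int Dp = D + 2, Hp = H + 2, Wp = W + 2;
  const size_t chan = (size_t)Dp * Hp * Wp;
  std::vector<double> acc(D);
  for (int co = 0; co < Cout; ++co) {
    double* yc = y + (size_t)D * H * W * co;
    const double* wc = w + (size_t)27 * Cin * co;
    for (int ww = 0; ww < W; ++ww)
      for (int hh = 0; hh < H; ++hh) {
        std::fill(acc.begin(), acc.end(), b[co]);
        for (int ci = 0; ci < Cin; ++ci) {
          const double* xc = xp + chan * ci;
          const double* wt = wc + 27 * ci;
          for (int kw = 0; kw < 3; ++kw)
            for (int kh = 0; kh < 3; ++kh) {
              const double* src = xc + (size_t)Dp * ((hh + kh) + (size_t)Hp * (ww + kw));
              const double w0 = wt[3 * (kh + 3 * kw)];
              const double w1 = wt[1 + 3 * (kh + 3 * kw)];
              const double w2 = wt[2 + 3 * (kh + 3 * kw)];
              for (int dd = 0; dd < D; ++dd)
                acc[dd] += w0 * src[dd] + w1 * src[dd + 1] + w2 * src[dd + 2];
            }
        }
        std::copy(acc.begin(), acc.end(), yc + (size_t)D * (hh + (size_t)H * ww));
      }
  }
}

// gw[k,ci,co] = sum_p xpad[p+k,ci] * gy[p,co]; gb[co] = sum_p gy[p,co]
void NAME(conv3s1_gw_core)(const double* xp, const double* gy, double* gw,
                           double* gb, int D, int H, int W, int Cin, int Cout) {
  const int Dp = D + 2, Hp = H + 2;
  const size_t N = (size_t)D * H * W;
  const size_t chan = (size_t)Dp * Hp * (W + 2);
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gy + N * co;
    double sb = 0.0;
    for (size_t i = 0; i < N; ++i) sb += gc[i];
    gb[co] = sb;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + chan * ci;
      double accw[27] = {0.0};
      for (int ww = 0; ww < W; ++ww)
        for (int hh = 0; hh < H; ++hh) {
          const double* g = gc + (size_t)D * (hh + (size_t)H * ww);
          for (int kw = 0; kw < 3; ++kw)
            for (int kh = 0; kh < 3; ++kh) {
              const double* src = xc + (size_t)Dp * ((hh + kh) + (size_t)Hp * (ww + kw));
              double a0 = 0, a1 = 0, a2 = 0;
              for (int dd = 0; dd < D; ++dd) {
                const double gv = g[dd];
                a0 += src[dd] * gv;
                a1 += src[dd + 1] * gv;
                a2 += src[dd + 2] * gv;
              }
              accw[3 * (kh + 3 * kw)] += a0;
              accw[1 + 3 * (kh + 3 * kw)] += a1;
              accw[2 + 3 * (kh + 3 * kw)] += a2;
            }
        }
      for (int k = 0; k < 27; ++k)
        gw[k + 27 * (ci + (size_t)Cin * co)] = accw[k];
    }
  }
}

// 4x4x4 stride-2 forward from a padded buffer.
void NAME(conv4s2_core)(const double* xp, const double* w, const double* b,
                        double* y, int D, int H, int W, int Cin, int Cout) {
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const int Dp = D + 2, Hp = H + 2, Wp = W + 2;
  const size_t chan = (size_t)Dp * Hp * Wp;
  std::vector<double> acc(Do);
  for (int co = 0; co < Cout; ++co) {
    double* yc = y + (size_t)Do * Ho * Wo * co;
    const double* wc = w + (size_t)64 * Cin * co;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        std::fill(acc.begin(), acc.end(), b[co]);
        for (int ci = 0; ci < Cin; ++ci) {
          const double* xc = xp + chan * ci;
          const double* wt = wc + 64 * ci;
          for (int kw = 0; kw < 4; ++kw)
            for (int kh = 0; kh < 4; ++kh) {
              const double* src =
                  xc + (size_t)Dp * ((2 * oh + kh) + (size_t)Hp * (2 * ow + kw));
              const double w0 = wt[0 + 4 * (kh + 4 * kw)];
              const double w1 = wt[1 + 4 * (kh + 4 * kw)];
              const double w2 = wt[2 + 4 * (kh + 4 * kw)];
              const double w3 = wt[3 + 4 * (kh + 4 * kw)];
              for (int od = 0; od < Do; ++od) {
                const double* s = src + 2 * od;
                acc[od] += w0 * s[0] + w1 * s[1] + w2 * s[2] + w3 * s[3];
              }
            }
        }
        std::copy(acc.begin(), acc.end(), yc + (size_t)Do * (oh + (size_t)Ho * ow));
      }
  }
}

// 4x4x4 stride-2 gradients; gxp (padded) may be null when the input
// gradient is not needed.
void NAME(conv4s2_grad_core)(const double* xp, const double* w,
                             const double* gy, double* gw, double* gb,
                             double* gxp, int D, int H, int W,
                             int Cin, int Cout) {
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const size_t No = (size_t)Do * Ho * Wo;
  const int Dp = D + 2, Hp = H + 2, Wp = W + 2;
  const size_t chan = (size_t)Dp * Hp * Wp;
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gy + No * co;
    double sb = 0.0;
    for (size_t i = 0; i < No; ++i) sb += gc[i];
    gb[co] = sb;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + chan * ci;
      double* gxc = gxp ? gxp + chan * ci : (double*)0;
      const double* wt = w + 64 * (ci + (size_t)Cin * co);
      double* gwt = gw + 64 * (ci + (size_t)Cin * co);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          const double* g = gc + (size_t)Do * (oh + (size_t)Ho * ow);
          for (int kw = 0; kw < 4; ++kw)
            for (int kh = 0; kh < 4; ++kh) {
              const size_t base =
                  (size_t)Dp * ((2 * oh + kh) + (size_t)Hp * (2 * ow + kw));
              const double* src = xc + base;
              double a0 = 0, a1 = 0, a2 = 0, a3 = 0;
              for (int od = 0; od < Do; ++od) {
                const double gv = g[od];
                const double* s = src + 2 * od;
                a0 += s[0] * gv; a1 += s[1] * gv;
                a2 += s[2] * gv; a3 += s[3] * gv;
              }
              gwt[0 + 4 * (kh + 4 * kw)] += a0;
              gwt[1 + 4 * (kh + 4 * kw)] += a1;
              gwt[2 + 4 * (kh + 4 * kw)] += a2;
              gwt[3 + 4 * (kh + 4 * kw)] += a3;
              if (gxc) {
                double* gdst = gxc + base;
                const double w0 = wt[0 + 4 * (kh + 4 * kw)];
                const double w1 = wt[1 + 4 * (kh + 4 * kw)];
                const double w2 = wt[2 + 4 * (kh + 4 * kw)];
                const double w3 = wt[3 + 4 * (kh + 4 * kw)];
                for (int od = 0; od < Do; ++od) {
                  const double gv = g[od];
                  double* t = gdst + 2 * od;
                  t[0] += w0 * gv; t[1] += w1 * gv;
                  t[2] += w2 * gv; t[3] += w3 * gv;
                }
              }
            }
        }
    }
  }
}
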